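# Cell construction: six-section geometry, passive properties, d_lambda
# compartmentalization, per-section channel densities, axial coupling and
# the perimembrane calcium pool.

#' Default cell configuration
#'
#' Loads the packaged cell config (geometry, passive constants, calcium
#' shell, noise and nicotinic parameters) and applies any overrides.
#'
#' @param ... Named overrides, e.g. `passive = list(e_leak_mV = -55)`;
#'   sub-lists are merged element-wise.
#' @return A nested list, class `pg_config`.
#' @export
cell_config <- function(...) {
  path <- system.file("extdata", "cell.yaml", package = "pgcell")
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pg_config")
}

#' d_lambda compartment count
#'
#' Chooses the number of compartments for a cylindrical section so that each
#' compartment is no longer than `d_lambda` times the AC length constant at
#' the reference frequency (the smallest odd integer satisfying this):
#' `lambda_f = 1e5 * sqrt(diam / (4 pi f Ra Cm))` (um, with diam in um,
#' f in Hz, Ra in ohm cm, Cm in uF/cm2).
#'
#' @param length_um,diam_um Section geometry, um.
#' @param ra Axial resistivity, ohm cm.
#' @param cm Membrane capacitance, uF/cm2.
#' @param d_lambda Fraction of the length constant (default 0.1).
#' @param freq Reference frequency, Hz (default 100).
#' @return Odd integer compartment count (>= 1).
#' @export
compartmentalize <- function(length_um, diam_um, ra = 173, cm = 1.2,
                             d_lambda = 0.1, freq = 100) {
  stopifnot(length_um > 0, diam_um > 0, ra > 0, cm > 0,
            d_lambda > 0, d_lambda <= 1, freq > 0)
  lambda_f <- 1e5 * sqrt(diam_um / (4 * pi * freq * ra * cm))
  as.integer(floor((length_um / (d_lambda * lambda_f) + 0.9) / 2) * 2 + 1)
}

# cross-sectional half-resistance of one compartment (ohm)
.half_res <- function(L_um, diam_um, ra) {
  ra * (L_um * 1e-4 / 2) / (pi * (diam_um * 1e-4 / 2)^2)
}

#' Build the six-section PG cell
#'
#' Assembles the compartmental model: soma (8 x 8 um), two 20 um dendrites,
#' a 1 um gemmule shaft and gemmule on dendrite 1, and a 50 um axon, all
#' joined per the published topology, discretized by the d_lambda rule and
#' loaded with the parameter set's channel densities.  Active channels are
#' expressed uniformly in all sections except the T-type calcium channel
#' (somatic by default, see `cat_scope` of [parameter_set()]) and the
#' nicotinic conductance (gemmule only unless `nic_scope = "all"`).
#'
#' @param params A [parameter_set()] (or preset, see [load_preset()]).
#' @param config A [cell_config()].
#' @param nseg_mult Integer factor multiplying every compartment count
#'   (spatial-grid refinement checks); default 1.
#' @return An object of class `pg_cell`: compartment table plus density
#'   matrices ready for [run_current_clamp()].
#' @export
build_cell <- function(params = parameter_set(), config = cell_config(),
                       nseg_mult = 1) {
  stopifnot(inherits(params, "pg_params"))
  geo <- config$geometry
  pas <- config$passive
  sections <- names(geo)
  need <- c("soma", "dend1", "dend2", "shaft", "gemmule", "axon")
  if (!setequal(sections, need)) stop("config geometry must have the six PG sections")

  nseg <- vapply(geo, function(g) {
    compartmentalize(g$L_um, g$diam_um, pas$ra_ohm_cm, pas$cm_uF_cm2,
                     config$d_lambda$fraction, config$d_lambda$frequency_Hz)
  }, integer(1))
  nseg <- nseg * as.integer(nseg_mult)

  # compartments in parent-before-child order (soma first)
  order_sec <- c("soma", "dend1", "dend2", "shaft", "gemmule", "axon")
  comp <- data.frame(section = character(0), seg = integer(0),
                     L_um = numeric(0), diam_um = numeric(0))
  parent <- integer(0)
  gax <- numeric(0)
  first_comp <- integer(0)  # index of first compartment per section
  names_first <- character(0)
  for (sec in order_sec) {
    g <- geo[[sec]]
    n <- nseg[[sec]]
    Lc <- g$L_um / n
    base <- nrow(comp)
    comp <- rbind(comp, data.frame(section = sec, seg = seq_len(n),
                                   L_um = Lc, diam_um = g$diam_um))
    first_comp <- c(first_comp, base + 1L)
    names_first <- c(names_first, sec)
    half <- .half_res(Lc, g$diam_um, pas$ra_ohm_cm)
    if (is.null(g$parent)) {
      parent <- c(parent, 0L, rep(0L, n - 1L))
      if (n > 1L) {
        parent[(base + 2L):(base + n)] <- (base + 1L):(base + n - 1L)
        gax <- c(gax, 0, rep(1 / (2 * half), n - 1L))
      } else {
        gax <- c(gax, 0)
      }
    } else {
      pidx <- first_comp[match(g$parent, names_first)]
      pgeo <- geo[[g$parent]]
      # attaching at a parent internal node (pos 0.5 with odd nseg) adds no
      # parent-side resistance; attaching at an end adds the parent's
      # half-compartment resistance
      pseg <- nseg[[g$parent]]
      if (isTRUE(all.equal(g$pos, 0.5))) {
        pidx <- pidx + (pseg - 1L) %/% 2L   # middle compartment
        phalf <- 0
      } else {
        pidx <- pidx + pseg - 1L            # distal compartment
        phalf <- .half_res(pgeo$L_um / pseg, pgeo$diam_um, pas$ra_ohm_cm)
      }
      parent <- c(parent, pidx, if (n > 1L) (base + 1L):(base + n - 1L))
      gax <- c(gax, 1 / (half + phalf), rep(1 / (2 * half), n - 1L))
    }
  }
  comp$parent <- parent
  comp$gax_S <- gax
  comp$area_cm2 <- pi * (comp$diam_um * 1e-4) * (comp$L_um * 1e-4)

  n <- nrow(comp)
  gbar <- matrix(0, n, length(.CHANNELS), dimnames = list(NULL, .CHANNELS))
  for (ch in .CHANNELS) gbar[, ch] <- params$gmax[[ch]]
  if (identical(params$cat_scope, "soma")) {
    gbar[comp$section != "soma", "CaT"] <- 0
  }
  gnic <- rep(0, n)
  if (isTRUE(params$nicotinic)) {
    g <- if (is.null(params$nic_g)) config$nicotinic$g_S_cm2 else params$nic_g
    if (identical(params$nic_scope, "all")) {
      # uniform expression at matched total conductance
      gnic[] <- g * sum(comp$area_cm2[comp$section == "gemmule"]) /
        sum(comp$area_cm2)
    } else {
      gnic[comp$section == "gemmule"] <- g
    }
  }

  structure(list(
    comp = comp,
    gbar = gbar,
    gleak = rep(pas$g_leak_S_cm2, n),
    eleak = rep(params$e_leak, n),
    gnic = gnic,
    cm = rep(pas$cm_uF_cm2, n),
    params = params,
    config = config
  ), class = "pg_cell")
}

#' @export
print.pg_cell <- function(x, ...) {
  cat("PG cell model (", nrow(x$comp), " compartments, ",
      length(unique(x$comp$section)), " sections)\n", sep = "")
  cat("parameter set:", x$params$label, "\n")
  cat("E_leak:", x$eleak[1], "mV; g_leak:",
      format(x$gleak[1], digits = 5), "S/cm2\n")
  tab <- stats::aggregate(area_cm2 ~ section, x$comp, sum)
  tab$n_comp <- table(x$comp$section)[tab$section]
  print(tab, row.names = FALSE)
  nz <- x$params$gmax[x$params$gmax > 0]
  cat("active conductances (S/cm2):\n")
  print(nz)
  invisible(x)
}

#' Resolved per-compartment conductance table
#'
#' @param cell A `pg_cell`.
#' @return data.frame: one row per compartment with geometry and every
#'   channel's local maximal conductance density (S/cm2).
#' @export
describe_cell <- function(cell) {
  stopifnot(inherits(cell, "pg_cell"))
  cbind(cell$comp,
        as.data.frame(cell$gbar),
        leak = cell$gleak, nic = cell$gnic, e_leak = cell$eleak)
}

# passive steady-state solve: absolute-conductance linear system
.passive_rin <- function(cell, g_leak = NULL) {
  comp <- cell$comp
  n <- nrow(comp)
  gl <- if (is.null(g_leak)) cell$gleak else rep(g_leak, n)
  A <- diag(gl * comp$area_cm2, n)
  for (i in seq_len(n)[-1]) {
    p <- comp$parent[i]
    g <- comp$gax_S[i]
    A[i, i] <- A[i, i] + g
    A[p, p] <- A[p, p] + g
    A[i, p] <- A[i, p] - g
    A[p, i] <- A[p, i] - g
  }
  b <- numeric(n)
  b[1] <- 1e-12 * 1e3  # 1 pA in mA units (S * mV = mA)
  v <- solve(A, b)     # deflection in mV
  v[1] / 1e-3          # mV per nA = MOhm
}

#' Calibrate the uniform leak conductance
#'
#' The leak density is the one free passive parameter; it is fixed by
#' requiring the passive cell's somatic input resistance (steady-state
#' deflection per unit injected current) to equal the target value.
#' Solved by root-finding on the passive steady-state system.
#'
#' @param config A [cell_config()].
#' @param target_rin Target somatic input resistance, MOhm.
#' @return Calibrated leak density, S/cm2.
#' @export
calibrate_leak <- function(config = cell_config(),
                           target_rin = config$passive$target_rin_MOhm) {
  cell <- build_cell(parameter_set(label = "passive"), config)
  f <- function(lg) .passive_rin(cell, g_leak = 10^lg) - target_rin
  r <- stats::uniroot(f, c(-6, -2), tol = 1e-12)
  10^r$root
}

#' Perimembrane calcium update
#'
#' Advances the submembrane calcium pool over one step of length `dt` under
#' a (constant) summed calcium current density:
#' `d[Ca]/dt = -1e4 * I_Ca / (2 F depth) - ([Ca] - basal)/tau`,
#' with influx only (an outward calcium current does not deplete the pool
#' below its basal level).  The update is the exact exponential solution for
#' constant drive.
#'
#' @param ca Current concentration, mM.
#' @param i_ca Summed calcium current density, mA/cm2 (inward negative).
#' @param dt Step, ms (> 0).
#' @param basal Basal concentration, mM.
#' @param tau Decay time constant, ms.
#' @param depth_um Shell depth, um.
#' @return Updated concentration, mM.
#' @export
calcium_step <- function(ca, i_ca, dt, basal = 2.4e-4, tau = 200,
                         depth_um = 0.1) {
  stopifnot(dt > 0, ca >= 0)
  drive <- pmax(0, -1e4 * i_ca / (2 * 96485.33212 * depth_um))  # mM/ms
  target <- basal + drive * tau
  target + (ca - target) * exp(-dt / tau)
}

#' Calcium reversal potential (Nernst)
#'
#' `E_Ca = (RT / 2F) ln([Ca]_o / [Ca]_i)`, recomputed per compartment and
#' time step in the simulator.
#'
#' @param ca_i Internal concentration, mM (> 0).
#' @param ca_o External concentration, mM (> 0; default 2 mM).
#' @param temp_K Temperature, K (default 296.15 K = 23 C).
#' @return Reversal potential, mV.
#' @export
calcium_reversal <- function(ca_i, ca_o = 2, temp_K = 296.15) {
  if (any(ca_i <= 0) || any(ca_o <= 0))
    stop("concentrations must be positive", call. = FALSE)
  vapply(ca_i, cpp_nernst_ca, numeric(1), cao = ca_o, tempK = temp_K)
}
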