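# Parameter sets: one maximal-conductance vector per electrophysiological
# phenotype, plus overrides (leak reversal, noise, nicotinic conductance).
# The nine published presets ship as plain-text configs under
# inst/extdata/presets/.

#' Construct a parameter set
#'
#' @param gmax Named numeric vector of maximal conductance densities
#'   (S/cm2) over any subset of `Na, K, KA, KCa, H, CaL, CaT, CAN`
#'   (parenthesised spellings accepted); unnamed channels default to 0.
#' @param e_leak Leak reversal potential, mV.
#' @param noise Enable the colored current-noise source.
#' @param nicotinic Enable the ohmic nicotinic conductance.
#' @param nic_g Nicotinic conductance density, S/cm2 (default from the cell
#'   config, 0.005).
#' @param nic_scope `"gemmule"` (default) or `"all"` (uniform expression at
#'   matched total conductance).
#' @param cat_scope Where the T-type calcium channel is expressed:
#'   `"all"` (default, uniform) or `"soma"` (restricted to the soma).
#' @param label Phenotype label.
#' @return Object of class `pg_params`.
#' @export
parameter_set <- function(gmax = numeric(0), e_leak = -70, noise = FALSE,
                          nicotinic = FALSE, nic_g = NULL,
                          nic_scope = "gemmule", cat_scope = "all",
                          label = "custom") {
  full <- stats::setNames(rep(0, length(.CHANNELS)), .CHANNELS)
  if (length(gmax)) {
    if (is.null(names(gmax)) || any(!nzchar(names(gmax))))
      stop("gmax must be a named vector", call. = FALSE)
    for (nm in names(gmax)) {
      cn <- channel_name(nm)
      if (gmax[[nm]] < 0) stop("negative conductance for ", cn, call. = FALSE)
      full[[cn]] <- as.numeric(gmax[[nm]])
    }
  }
  stopifnot(is.finite(e_leak), cat_scope %in% c("soma", "all"),
            nic_scope %in% c("gemmule", "all"))
  structure(list(gmax = full, e_leak = e_leak, noise = isTRUE(noise),
                 nicotinic = isTRUE(nicotinic), nic_g = nic_g,
                 nic_scope = nic_scope, cat_scope = cat_scope,
                 label = label),
            class = "pg_params")
}

#' @export
print.pg_params <- function(x, ...) {
  cat("PG parameter set:", x$label, "\n")
  cat("  E_leak:", x$e_leak, "mV | noise:", x$noise,
      "| nicotinic:", x$nicotinic, "| Ca(T) scope:", x$cat_scope, "\n")
  nz <- x$gmax[x$gmax > 0]
  if (length(nz)) {
    cat("  Gmax (S/cm2):",
        paste(names(nz), format(nz, digits = 4), sep = "=", collapse = ", "),
        "\n")
  } else cat("  passive (all Gmax = 0)\n")
  invisible(x)
}

#' Available preset keys
#' @return Character vector of figure-keyed preset names.
#' @export
preset_keys <- function() {
  files <- list.files(system.file("extdata", "presets", package = "pgcell"),
                      pattern = "\\.yaml$")
  sort(sub("\\.yaml$", "", files))
}

#' Load a published preset
#'
#' Returns the exact published conductance row and the current-clamp
#' protocol pair from the corresponding figure legend.  `fig2A`
#' additionally carries the depolarized leak reversal (-55 mV) it requires;
#' `fig2D` carries `noise = TRUE`.
#'
#' @param key One of [preset_keys()] (`fig2A` ... `fig3E`).
#' @return List with elements `params` ([parameter_set()]) and `protocol`
#'   (class `pg_protocol_pair`: `depol` and `hyperpol` step descriptors and
#'   a post-stimulus window).
#' @export
load_preset <- function(key) {
  path <- system.file("extdata", "presets", paste0(key, ".yaml"),
                      package = "pgcell")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown preset key: '", key, "' (see preset_keys())", call. = FALSE)
  raw <- yaml::read_yaml(path)
  params <- parameter_set(
    gmax = unlist(raw$gmax_S_cm2),
    e_leak = raw$e_leak_mV,
    noise = raw$noise,
    nicotinic = raw$nicotinic,
    label = raw$label)
  protocol <- structure(list(
    key = raw$key,
    depol = list(amp_pA = raw$protocol$depol$amp_pA,
                 dur_ms = raw$protocol$depol$dur_ms),
    hyperpol = list(amp_pA = raw$protocol$hyperpol$amp_pA,
                    dur_ms = raw$protocol$hyperpol$dur_ms),
    post_ms = raw$protocol$post_ms), class = "pg_protocol_pair")
  list(params = params, protocol = protocol, key = raw$key,
       response_type = raw$response_type, label = raw$label)
}

#' Serialize a parameter set
#'
#' Round-trips exactly through [read_parameter_set()].
#'
#' @param params A `pg_params`.
#' @param file Output path (YAML).
#' @return `file`, invisibly.
#' @export
write_parameter_set <- function(params, file) {
  stopifnot(inherits(params, "pg_params"))
  x <- unclass(params)
  x$gmax <- as.list(x$gmax)
  yaml::write_yaml(x, file, precision = 17)
  invisible(file)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(file) {
  x <- yaml::read_yaml(file)
  parameter_set(gmax = unlist(x$gmax), e_leak = x$e_leak, noise = x$noise,
                nicotinic = x$nicotinic,
                nic_g = if (!is.null(x$nic_g)) x$nic_g,
                nic_scope = x$nic_scope, cat_scope = x$cat_scope,
                label = x$label)
}

#' Scale channel conductances (pharmacological block)
#'
#' Returns a copy of the parameter set with the named channels' maximal
#' conductances multiplied by the given factors (0 = full block, as with
#' QX314 for the fast sodium current or nickel for the T-type calcium
#' current); nothing else changes.
#'
#' @param params A `pg_params`.
#' @param block Named numeric vector of scale factors in `[0, 1]`, e.g.
#'   `c(Na = 0)`.
#' @return Modified copy of `params`.
#' @export
apply_pharmacology <- function(params, block) {
  stopifnot(inherits(params, "pg_params"), length(block) > 0)
  if (is.null(names(block))) stop("block must be named", call. = FALSE)
  if (any(block < 0 | block > 1))
    stop("scale factors must lie in [0, 1]", call. = FALSE)
  out <- params
  for (nm in names(block)) {
    cn <- channel_name(nm)
    out$gmax[[cn]] <- out$gmax[[cn]] * block[[nm]]
  }
  out
}

#' Enable or disable the nicotinic conductance
#'
#' An ohmic cation conductance (reversal +3.2 mV) expressed in the gemmule
#' (dendritic spine) by default, 5 mS/cm2 when enabled.
#'
#' @param params A `pg_params`.
#' @param enabled Logical.
#' @param g Conductance density, S/cm2 (default 0.005).
#' @param scope `"gemmule"` or `"all"` (uniform, matched total conductance).
#' @return Modified copy of `params`.
#' @export
set_nicotinic <- function(params, enabled = TRUE, g = 0.005,
                          scope = "gemmule") {
  stopifnot(inherits(params, "pg_params"), g >= 0)
  params$nicotinic <- isTRUE(enabled)
  params$nic_g <- g
  params$nic_scope <- scope
  params
}

#' Elementwise ratio span of two presets' voltage-dependent conductances
#'
#' Ratios `b/a` over the channels with nonzero conductance in both sets,
#' restricted to voltage-dependent mechanisms (the calcium-gated K(Ca) and
#' CAN conductances and the ohmic leak/nicotinic ones are excluded).
#'
#' @param a,b `pg_params` objects (denominator, numerator).
#' @return List with `ratios` (named), `min`, `max`.
#' @export
conductance_ratio_span <- function(a, b) {
  stopifnot(inherits(a, "pg_params"), inherits(b, "pg_params"))
  vdep <- c("Na", "K", "KA", "H", "CaL", "CaT")
  shared <- vdep[a$gmax[vdep] > 0 & b$gmax[vdep] > 0]
  r <- b$gmax[shared] / a$gmax[shared]
  list(ratios = r, min = min(r), max = max(r))
}
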