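#' Von Bertalanffy growth parameter set
#'
#' Bundle the three von Bertalanffy growth function (VBGF) parameters for one
#' species and sex. The VBGF is \eqn{L(t) = L_\infty (1 - e^{-k (t - t_0)})},
#' the standard fish length-at-age model; here it is also inverted to estimate
#' age from an observed fork length.
#'
#' Parameter values are always runtime inputs (typically read from a registry
#' file with [read_vbgf_registry()]): growth-curve fits come from dedicated
#' age-and-growth studies and differ by species, sex and region, so nothing is
#' hard-coded.
#'
#' @param species Taxon label, e.g. `"R. terraenovae"`.
#' @param sex One of `"female"`, `"male"`, `"combined"`.
#' @param L_inf Asymptotic fork length, mm. Must be positive and finite.
#' @param k Growth coefficient, per year. Must be positive and finite.
#' @param t0 Theoretical age at zero length, years. Finite; usually negative.
#' @param source Optional provenance note (which growth study the fit is from).
#'
#' @return An object of class `vbgf_params`.
#' @examples
#' p <- vbgf_params("R. terraenovae", "male", L_inf = 900, k = 0.5, t0 = -1)
#' length_at_age(p, 2.008155)
#' age_at_length(p, 700)
#' @seealso [length_at_age()], [age_at_length()], [read_vbgf_registry()]
#' @export
vbgf_params <- function(species, sex, L_inf, k, t0, source = NA_character_) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  sex <- match.arg(sex, c("female", "male", "combined"))
  if (!is.numeric(L_inf) || length(L_inf) != 1L || !is.finite(L_inf) || L_inf <= 0)
    stop("'L_inf' must be a single finite positive number (mm)")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("'k' must be a single finite positive number (per year)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("'t0' must be a single finite number (years)")
  structure(
    list(species = species, sex = sex,
         L_inf = as.numeric(L_inf), k = as.numeric(k), t0 = as.numeric(t0),
         source = source),
    class = "vbgf_params"
  )
}

#' @export
print.vbgf_params <- function(x, ...) {
  cat(sprintf("VBGF parameters: %s (%s)\n", x$species, x$sex))
  cat(sprintf("  L_inf = %g mm, k = %g /yr, t0 = %g yr\n", x$L_inf, x$k, x$t0))
  if (!is.na(x$source)) cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

#' Fork length at age under the VBGF
#'
#' Forward von Bertalanffy curve
#' \eqn{L(t) = L_\infty (1 - e^{-k (t - t_0)})}. Used by the simulator to grow
#' individuals and by round-trip tests of the inverse.
#'
#' @param params A [vbgf_params()] object.
#' @param age Age in years (vectorised). Must satisfy `age >= t0`.
#' @return Fork length in mm, in `[0, L_inf)`, strictly increasing in age.
#' @export
length_at_age <- function(params, age) {
  stopifnot(inherits(params, "vbgf_params"), is.numeric(age))
  if (any(age < params$t0, na.rm = TRUE))
    stop(sprintf("age below t0 = %g implies negative length", params$t0))
  params$L_inf * -expm1(-params$k * (age - params$t0))
}

#' Backtransform fork length to age under the VBGF
#'
#' Inverts the von Bertalanffy curve:
#' \deqn{\mathrm{Age} = \frac{\ln(1 - L_t / L_\infty)}{-k} + t_0}
#' giving the average age at which a fish of the given fork length is expected
#' under the growth curve. Exact inverse of [length_at_age()].
#'
#' Lengths at or above `L_inf` have no finite age under the curve; they raise
#' an error here, and the pipeline layer ([backtransform_record()]) instead
#' flags such records non-backtransformable (possible with angler-estimated
#' lengths). `length = 0` is accepted and returns `t0`.
#'
#' @param params A [vbgf_params()] object.
#' @param length Fork length in mm (vectorised), `0 <= length < L_inf`.
#' @return Age in years.
#' @export
age_at_length <- function(params, length) {
  stopifnot(inherits(params, "vbgf_params"), is.numeric(length))
  if (any(length < 0, na.rm = TRUE))
    stop("negative fork length")
  if (any(length >= params$L_inf, na.rm = TRUE))
    stop(sprintf(
      "fork length >= L_inf (%g mm): record is non-backtransformable", params$L_inf))
  log1p(-length / params$L_inf) / (-params$k) + params$t0
}

#' Build a VBGF parameter registry
#'
#' A registry holds one [vbgf_params()] set per (species, sex) pair and is the
#' lookup table the pipeline uses to backtransform each shark's length with
#' the growth curve matching its species and sex.
#'
#' @param ... `vbgf_params` objects.
#' @return An object of class `vbgf_registry` (a named list keyed
#'   `"species|sex"`).
#' @examples
#' reg <- vbgf_registry(
#'   vbgf_params("R. terraenovae", "male", 900, 0.5, -1),
#'   vbgf_params("R. terraenovae", "female", 950, 0.45, -1.1)
#' )
#' lookup_vbgf(reg, "R. terraenovae", "male")
#' @export
vbgf_registry <- function(...) {
  entries <- list(...)
  if (length(entries) && is.list(entries[[1]]) && !inherits(entries[[1]], "vbgf_params") &&
      length(entries) == 1L)
    entries <- entries[[1]]
  ok <- vapply(entries, inherits, logical(1), what = "vbgf_params")
  if (!all(ok)) stop("all registry entries must be 'vbgf_params' objects")
  keys <- vapply(entries, function(p) paste(p$species, p$sex, sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (species, sex) pair in registry: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  names(entries) <- keys
  structure(entries, class = "vbgf_registry")
}

#' @export
print.vbgf_registry <- function(x, ...) {
  cat(sprintf("VBGF parameter registry (%d entries)\n", length(x)))
  for (p in x)
    cat(sprintf("  %-24s %-8s L_inf=%g k=%g t0=%g\n",
                p$species, p$sex, p$L_inf, p$k, p$t0))
  invisible(x)
}

#' Look up growth parameters for a species and sex
#'
#' Sharks of unknown sex fall back to the `"combined"` parameter set when one
#' is registered; otherwise the lookup fails (and the pipeline flags the
#' record non-backtransformable).
#'
#' @param registry A [vbgf_registry()].
#' @param species,sex Keys to look up; `sex = "unknown"` triggers the
#'   combined-set fallback.
#' @return A `vbgf_params` object, or `NULL` if no set matches.
#' @export
lookup_vbgf <- function(registry, species, sex) {
  stopifnot(inherits(registry, "vbgf_registry"))
  if (identical(sex, "unknown")) sex <- "combined"
  registry[[paste(species, sex, sep = "|")]]
}

#' Read / write a VBGF parameter registry file
#'
#' The registry file is YAML: a list of blocks, each with `species`, `sex`,
#' `L_inf`, `k`, `t0` and an optional `source` provenance note. Values written
#' by [write_vbgf_registry()] read back identically (round trip).
#'
#' @param path Path to the YAML registry file.
#' @return For `read_vbgf_registry`, a [vbgf_registry()]; for
#'   `write_vbgf_registry`, `path`, invisibly.
#' @examples
#' reg <- vbgf_registry(vbgf_params("R. terraenovae", "male", 900, 0.5, -1))
#' f <- tempfile(fileext = ".yaml")
#' write_vbgf_registry(reg, f)
#' read_vbgf_registry(f)
#' @export
read_vbgf_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$parameters)) stop("registry file has no 'parameters' list: ", path)
  entries <- lapply(raw$parameters, function(b) {
    need <- c("species", "sex", "L_inf", "k", "t0")
    miss <- setdiff(need, names(b))
    if (length(miss))
      stop("registry block missing field(s): ", paste(miss, collapse = ", "))
    vbgf_params(b$species, b$sex, b$L_inf, b$k, b$t0,
                source = if (is.null(b$source)) NA_character_ else b$source)
  })
  vbgf_registry(entries)
}

#' @param registry A [vbgf_registry()] to write.
#' @rdname read_vbgf_registry
#' @export
write_vbgf_registry <- function(registry, path) {
  stopifnot(inherits(registry, "vbgf_registry"))
  blocks <- lapply(unclass(registry), function(p) {
    b <- list(species = p$species, sex = p$sex,
              L_inf = p$L_inf, k = p$k, t0 = p$t0)
    if (!is.na(p$source)) b$source <- p$source
    b
  })
  names(blocks) <- NULL
  yaml::write_yaml(list(parameters = blocks), path, precision = 15)
  invisible(path)
}
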