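#' Fragment-length models
#'
#' Parametric models for cfDNA fragment-length distributions. Sampled lengths
#' are always integers in the biologically plausible support \[70, 500\] bp:
#' mononucleosomal cfDNA peaks near 167 bp and capture-based libraries carry
#' essentially nothing outside this window.
#'
#' Three families are provided:
#' * `frag_point(length)` — a point mass (all fragments one length); used for
#'   exact end-to-end fixtures.
#' * `frag_normal(mean, sd)` — a discretized normal: integer probabilities
#'   proportional to the normal density mass in \[l - 0.5, l + 0.5\], truncated
#'   to \[70, 500\]. The default wild-type model is `frag_normal(168, 10)`,
#'   matching the mononucleosomal cfDNA mode.
#' * `frag_mixture(models, weights)` — a finite mixture, e.g. for dual-peak
#'   mutant profiles such as 158/191.
#'
#' @param length integer fragment length in bp (70-500).
#' @param mean,sd mean and standard deviation in bp, `sd > 0`.
#' @param models list of length models.
#' @param weights non-negative mixture weights summing to 1 (tolerance 1e-9).
#' @return An object of class `length_model`.
#' @examples
#' sample_lengths(frag_normal(168, 10), 5, seed = 1)
#' @name length_model
NULL

FRAG_LEN_MIN <- 70L
FRAG_LEN_MAX <- 500L

#' @rdname length_model
#' @export
frag_point <- function(length) {
  length <- as.integer(length)
  stopifnot(length(length) == 1L, !is.na(length))
  if (length < FRAG_LEN_MIN || length > FRAG_LEN_MAX)
    stop("point length must lie in [", FRAG_LEN_MIN, ", ", FRAG_LEN_MAX, "]")
  structure(list(kind = "point", length = length), class = "length_model")
}

#' @rdname length_model
#' @export
frag_normal <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  structure(list(kind = "discrete_normal", mean = mean, sd = sd),
            class = "length_model")
}

#' @rdname length_model
#' @export
frag_mixture <- function(models, weights) {
  stopifnot(is.list(models), length(models) == length(weights))
  if (!all(vapply(models, inherits, logical(1), "length_model")))
    stop("all mixture components must be length_model objects")
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  structure(list(kind = "mixture", models = models, weights = weights),
            class = "length_model")
}

# probability mass over the integer support 70:500
length_model_pmf <- function(model) {
  support <- FRAG_LEN_MIN:FRAG_LEN_MAX
  p <- switch(model$kind,
    point = as.numeric(support == model$length),
    discrete_normal = {
      m <- stats::pnorm(support + 0.5, model$mean, model$sd) -
        stats::pnorm(support - 0.5, model$mean, model$sd)
      if (sum(m) <= 0) stop("discrete normal has no mass on [70, 500]")
      m
    },
    mixture = {
      comp <- vapply(model$models, length_model_pmf, numeric(length(support)))
      as.numeric(comp %*% model$weights)
    },
    stop("unknown length model kind: ", model$kind)
  )
  p / sum(p)
}

#' Sample fragment lengths from a length model
#'
#' @param model a `length_model`.
#' @param n number of lengths to draw.
#' @param seed optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return Integer vector of `n` lengths in \[70, 500\].
#' @export
sample_lengths <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "length_model"), n >= 0)
  if (n == 0L) return(integer(0))
  draw <- function() {
    if (model$kind == "point") return(rep(model$length, n))
    support <- FRAG_LEN_MIN:FRAG_LEN_MAX
    sample(support, n, replace = TRUE, prob = length_model_pmf(model))
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# build a length model from a plain list, e.g. parsed YAML:
# list(kind="point", length=146) / list(kind="discrete_normal", mean=, sd=) /
# list(kind="mixture", components=list(...), weights=c(...))
model_from_config <- function(cfg) {
  if (inherits(cfg, "length_model")) return(cfg)
  if (is.null(cfg$kind)) stop("length model config needs a 'kind' field")
  switch(cfg$kind,
    point = frag_point(cfg$length),
    discrete_normal = frag_normal(cfg$mean, cfg$sd),
    mixture = frag_mixture(lapply(cfg$components, model_from_config),
                           unlist(cfg$weights)),
    stop("unknown length model kind: ", cfg$kind))
}
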