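#' Fragment-size gates
#'
#' A gate set is an ordered collection of non-overlapping length bands used
#' for in-silico size selection, mirroring gel-band extraction. Bands cut
#' from one gel share boundaries, so the convention here makes gates
#' partition: every gate is closed below and open above except the terminal
#' gate (the one with the largest upper bound), which is closed above. The
#' default gates are `[130, 160)` and `[160, 230]` bp — a boundary fragment
#' of exactly 160 bp falls in the upper band only.
#'
#' @param spec either a string like `"130-160,160-230"` or a list of
#'   two-element numeric vectors `c(lo, hi)`.
#' @return A `size_gates` data.frame with columns `lo`, `hi`, `terminal`.
#' @examples
#' size_gates("130-160,160-230")
#' @export
size_gates <- function(spec = "130-160,160-230") {
  if (is.character(spec)) {
    stopifnot(length(spec) == 1L)
    parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("gates must be 'lo-hi' pairs")
    spec <- lapply(parts, function(p) suppressWarnings(as.numeric(p)))
  }
  lo <- vapply(spec, `[`, numeric(1), 1L)
  hi <- vapply(spec, `[`, numeric(1), 2L)
  if (anyNA(lo) || anyNA(hi)) stop("non-numeric gate bound")
  if (any(lo >= hi)) stop("each gate needs lo < hi")
  g <- data.frame(lo = as.integer(lo), hi = as.integer(hi))
  g <- g[order(g$lo), , drop = FALSE]
  g$terminal <- g$hi == max(g$hi)
  # non-overlap under the lower-closed convention: next lo >= previous hi
  if (nrow(g) > 1L && any(g$lo[-1L] < g$hi[-nrow(g)]))
    stop("gates overlap")
  rownames(g) <- NULL
  class(g) <- c("size_gates", "data.frame")
  g
}

# gate index for each length (NA = outside all gates)
gate_membership <- function(length, gates) {
  idx <- rep(NA_integer_, length(length))
  for (k in seq_len(nrow(gates))) {
    inside <- length >= gates$lo[k] &
      (if (gates$terminal[k]) length <= gates$hi[k] else length < gates$hi[k])
    idx[inside & is.na(idx)] <- k
  }
  idx
}

#' Subset typed fragments to one size gate
#'
#' @param typed a typed-fragment data.frame (from [type_fragments()]).
#' @param gate a 1-row subset of a [size_gates()] table.
#' @return The rows of `typed` whose length falls inside the gate. Unresolved
#'   fragments pass gating like any other (gating is purely by length); they
#'   remain excluded from MAF.
#' @export
apply_gate <- function(typed, gate) {
  stopifnot(nrow(gate) == 1L)
  typed[!is.na(gate_membership(typed$length, gate)), , drop = FALSE]
}

#' Size-selection report: per-gate MAF and enrichment
#'
#' Applies a gate set to the typed fragments of one locus and reports, per
#' gate, the gated allele counts, the gated MAF, and the enrichment ratio
#' (gated MAF / ungated MAF) — the in-silico analogue of re-quantifying a
#' gel-extracted size band. Rows for fragments outside every gate and for the
#' ungated total are appended so counts are conserved across the partition.
#' A gate that captures no typed fragment reports `NA` (undefined) MAF, not
#' zero; enrichment is `NA` whenever it is undefined (ungated MAF zero, or
#' gated MAF undefined).
#'
#' @param typed typed-fragment data.frame for one locus.
#' @param gates a [size_gates()] table.
#' @return A data.frame with one row per gate plus `outside` and `ungated`
#'   rows: `gate`, `lo`, `hi`, `n_mut`, `n_wt`, `n_unresolved`, `maf`,
#'   `enrichment`.
#' @export
gate_report <- function(typed, gates = size_gates()) {
  stopifnot(nrow(typed) >= 1L)
  idx <- gate_membership(typed$length, gates)
  n_mut_all <- sum(typed$allele == "mutant")
  n_wt_all <- sum(typed$allele == "wild")
  maf_ungated <- if (n_mut_all + n_wt_all > 0)
    n_mut_all / (n_mut_all + n_wt_all) else NA_real_

  one_row <- function(label, lo, hi, rows) {
    n_mut <- sum(typed$allele[rows] == "mutant")
    n_wt <- sum(typed$allele[rows] == "wild")
    n_un <- sum(typed$allele[rows] == "unresolved")
    maf <- if (n_mut + n_wt > 0) n_mut / (n_mut + n_wt) else NA_real_
    enr <- if (!is.na(maf) && !is.na(maf_ungated) && maf_ungated > 0)
      maf / maf_ungated else NA_real_
    data.frame(gate = label, lo = lo, hi = hi, n_mut = n_mut, n_wt = n_wt,
               n_unresolved = n_un, maf = maf, enrichment = enr,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(gates)), function(k) {
    lab <- sprintf("[%d,%d%s", gates$lo[k], gates$hi[k],
                   if (gates$terminal[k]) "]" else ")")
    one_row(lab, gates$lo[k], gates$hi[k], which(!is.na(idx) & idx == k))
  })
  out <- do.call(rbind, c(rows,
    list(one_row("outside", NA, NA, which(is.na(idx)))),
    list(one_row("ungated", NA, NA, seq_len(nrow(typed))))))
  rownames(out) <- NULL
  out
}
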