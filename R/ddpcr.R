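#' Droplet digital PCR counts
#'
#' One ddPCR observation: the total number of droplets read and the number
#' positive on the mutant and wild channels, with the droplet volume (1 nL
#' for the QX-class instruments modeled here).
#'
#' @param n_total total droplets (> 0).
#' @param n_mut_pos,n_wt_pos positive droplets per channel, each in
#'   `[0, n_total]`.
#' @param droplet_volume droplet volume in nL (default 1).
#' @return A `droplet_counts` object.
#' @export
droplet_counts <- function(n_total, n_mut_pos, n_wt_pos, droplet_volume = 1) {
  stopifnot(n_total > 0, n_mut_pos >= 0, n_wt_pos >= 0,
            n_mut_pos <= n_total, n_wt_pos <= n_total, droplet_volume > 0)
  structure(list(n_total = as.numeric(n_total),
                 n_mut_pos = as.numeric(n_mut_pos),
                 n_wt_pos = as.numeric(n_wt_pos),
                 droplet_volume = droplet_volume),
            class = "droplet_counts")
}

#' Poisson occupancy rate from positive-droplet counts
#'
#' Template molecules distribute over droplets approximately Poisson, so the
#' fraction of negative droplets estimates `exp(-lambda)` and
#' `lambda = -ln(1 - n_pos / n_total)` is the mean template count per
#' droplet. This correction matters at high occupancy: at `lambda = 1` only
#' ~63.2% of droplets are positive, and the naive positive fraction would
#' understate the concentration by a third.
#'
#' @param n_pos positive droplets (`0 <= n_pos <= n_total`).
#' @param n_total total droplets (> 0).
#' @return The rate `lambda >= 0`. A fully positive channel is saturated
#'   (`lambda` infinite) and raises an error rather than clamping.
#' @examples
#' poisson_lambda(632121, 1e6)  # ~1.0
#' @export
poisson_lambda <- function(n_pos, n_total) {
  stopifnot(n_total > 0, n_pos >= 0, n_pos <= n_total)
  if (n_pos == n_total) stop("saturated channel")
  -log1p(-n_pos / n_total)
}

#' ddPCR quantification: concentrations and mutant allele frequency
#'
#' Inverts the Poisson occupancy model on each channel and reports per-channel
#' rates, concentrations (copies per nL), and the mutant allele frequency
#' `maf = lambda_mut / (lambda_mut + lambda_wt)`. The MAF is invariant to the
#' droplet volume, which only scales the concentrations.
#'
#' @param counts a [droplet_counts()] object.
#' @return A `ddpcr_estimate` list: `lambda_mut`, `lambda_wt`, `conc_mut`,
#'   `conc_wt` (copies/nL), `maf_ddpcr`.
#' @examples
#' ddpcr_maf(droplet_counts(20000, 150, 9000))
#' @export
ddpcr_maf <- function(counts) {
  stopifnot(inherits(counts, "droplet_counts"))
  lambda_mut <- poisson_lambda(counts$n_mut_pos, counts$n_total)
  lambda_wt <- poisson_lambda(counts$n_wt_pos, counts$n_total)
  if (lambda_mut + lambda_wt == 0) stop("no template detected")
  structure(list(
    lambda_mut = lambda_mut, lambda_wt = lambda_wt,
    conc_mut = lambda_mut / counts$droplet_volume,
    conc_wt = lambda_wt / counts$droplet_volume,
    maf_ddpcr = lambda_mut / (lambda_mut + lambda_wt)
  ), class = "ddpcr_estimate")
}

#' Read a droplet-count table from TSV
#'
#' Columns: `sample`, `n_total`, `n_mut_pos`, `n_wt_pos`, and optionally
#' `droplet_volume` (nL, default 1). `#`-prefixed lines are ignored.
#'
#' @param path TSV path.
#' @return A data.frame, one row per sample.
#' @export
read_droplet_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("sample", "n_total", "n_mut_pos", "n_wt_pos")
  if (!all(required %in% names(df)))
    stop("droplet counts TSV needs columns: ", paste(required, collapse = ", "))
  if (is.null(df$droplet_volume)) df$droplet_volume <- 1
  df
}

#' Quantify a table of ddPCR samples
#'
#' Runs [ddpcr_maf()] on every row; rows that cannot be quantified (saturated
#' channel, no template) carry the error message in the `error` column and
#' `NA` estimates, and do not stop the run.
#'
#' @param df a data.frame as returned by [read_droplet_counts()].
#' @return `df` with columns `lambda_mut`, `lambda_wt`, `conc_mut`,
#'   `conc_wt`, `maf_ddpcr`, `error` appended.
#' @export
ddpcr_table <- function(df) {
  est <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch({
      e <- ddpcr_maf(droplet_counts(df$n_total[i], df$n_mut_pos[i],
                                    df$n_wt_pos[i], df$droplet_volume[i]))
      data.frame(lambda_mut = e$lambda_mut, lambda_wt = e$lambda_wt,
                 conc_mut = e$conc_mut, conc_wt = e$conc_wt,
                 maf_ddpcr = e$maf_ddpcr, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(lambda_mut = NA_real_, lambda_wt = NA_real_,
                 conc_mut = NA_real_, conc_wt = NA_real_,
                 maf_ddpcr = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  cbind(df, do.call(rbind, est))
}
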