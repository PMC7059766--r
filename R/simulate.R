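#' Simulate a cfDNA fragment population at a hotspot
#'
#' Draws `n_templates` DNA fragments spanning a hotspot, each labelled mutant
#' or wild and given a length from the corresponding model. This is the
#' synthetic stand-in for a deep-coverage plasma sequencing library: defaults
#' emulate 151 bp paired-end reads and a wild-type distribution peaked at the
#' mononucleosomal 168 bp.
#'
#' Every fragment is placed so that it spans the hotspot position: the 0-based
#' start is uniform over `[pos - L, pos - 1]` (clipped at 0), where `L` is the
#' fragment length, so each fragment covers the variant base.
#'
#' Allele assignment is either `"deterministic"` — exactly
#' `round(true_maf * n_templates)` mutant fragments, which makes downstream
#' recovery checks exact — or `"binomial"` — each template mutant
#' independently with probability `true_maf`.
#'
#' @param hotspot a single-row `hotspot_panel` (or a 1-row subset of one).
#' @param true_maf true mutant allele fraction in \[0, 1\].
#' @param n_templates number of fragments to draw.
#' @param wild_model,mutant_model `length_model`s for the two alleles;
#'   `mutant_model` may be `NULL` only when `true_maf = 0`.
#' @param read_length sequenced read length in bp (default 151, >= 20).
#' @param allele_assignment `"deterministic"` or `"binomial"`.
#' @param seed integer seed; the output is a pure function of the arguments.
#' @return A data.frame with one row per fragment: `allele` ("mutant"/"wild"),
#'   `length` (bp), `start` (0-based fragment start). Carries the hotspot and
#'   read length as attributes for [fragments_to_sam()].
#' @examples
#' hs <- hotspot_panel("EGFR-T790M", "EGFR", "sim1", 600, "C", "T")
#' frags <- simulate_fragments(hs, true_maf = 0.5, n_templates = 10,
#'                             wild_model = frag_point(167),
#'                             mutant_model = frag_point(146), seed = 1)
#' table(frags$allele)
#' @export
simulate_fragments <- function(hotspot, true_maf, n_templates,
                               wild_model = frag_normal(168, 10),
                               mutant_model = NULL,
                               read_length = 151L,
                               allele_assignment = c("deterministic", "binomial"),
                               seed = 1L) {
  hotspot <- as_single_hotspot(hotspot)
  allele_assignment <- match.arg(allele_assignment)
  stopifnot(true_maf >= 0, true_maf <= 1, n_templates >= 1)
  read_length <- as.integer(read_length)
  if (read_length < 20L) stop("read_length must be >= 20 bp")
  if (true_maf > 0 && is.null(mutant_model))
    stop("mutant_model is required when true_maf > 0")

  out <- withr::with_seed(as.integer(seed), {
    n_mut <- if (allele_assignment == "deterministic") {
      as.integer(round(true_maf * n_templates))
    } else {
      stats::rbinom(1L, n_templates, true_maf)
    }
    allele <- rep("wild", n_templates)
    if (n_mut > 0) allele[sample.int(n_templates, n_mut)] <- "mutant"
    len <- integer(n_templates)
    if (n_mut > 0)
      len[allele == "mutant"] <- sample_lengths(mutant_model, n_mut)
    len[allele == "wild"] <- sample_lengths(wild_model, n_templates - n_mut)
    pos0 <- hotspot$pos - 1L  # 0-based variant position
    lo <- pmax(0L, pos0 - len + 1L)
    start <- lo + floor(stats::runif(n_templates) * (pos0 - lo + 1L))
    data.frame(allele = allele, length = len, start = as.integer(start),
               stringsAsFactors = FALSE)
  })
  attr(out, "hotspot") <- hotspot
  attr(out, "read_length") <- read_length
  out
}

as_single_hotspot <- function(hotspot) {
  if (is.data.frame(hotspot)) {
    if (nrow(hotspot) != 1L) stop("a single hotspot (1 row) is required")
    return(validate_panel(hotspot)[1L, ])
  }
  stop("hotspot must be a 1-row hotspot_panel")
}

#' Simulate droplet digital PCR partitioning
#'
#' Templates are partitioned into `n_droplets` droplets; per-droplet mutant
#' and wild template counts are independent Poisson draws with means
#' `lambda_mut` and `lambda_wt`. A droplet is positive on a channel when it
#' holds at least one template of that class — the occupancy observation the
#' Poisson quantification model inverts.
#'
#' @param n_droplets number of droplets.
#' @param lambda_mut,lambda_wt mean templates per droplet (>= 0, finite).
#' @param droplet_volume droplet volume in nL (default 1).
#' @param seed integer seed.
#' @return A `droplet_counts` object (see [droplet_counts()]).
#' @export
simulate_droplets <- function(n_droplets, lambda_mut, lambda_wt,
                              droplet_volume = 1, seed = 1L) {
  stopifnot(n_droplets >= 1,
            is.finite(lambda_mut), lambda_mut >= 0,
            is.finite(lambda_wt), lambda_wt >= 0)
  withr::with_seed(as.integer(seed), {
    n_mut_pos <- sum(stats::rpois(n_droplets, lambda_mut) > 0L)
    n_wt_pos <- sum(stats::rpois(n_droplets, lambda_wt) > 0L)
    droplet_counts(n_total = n_droplets, n_mut_pos = n_mut_pos,
                   n_wt_pos = n_wt_pos, droplet_volume = droplet_volume)
  })
}
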