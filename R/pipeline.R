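#' Summarize the typed fragments of one locus
#'
#' Combines allele counts, NGS MAF, per-allele length profiles, the frequency
#' bin and the Short/Long/Normal/Other description into one per-hotspot
#' result.
#'
#' @param typed typed-fragment data.frame from [type_fragments()].
#' @param hotspot a 1-row `hotspot_panel`.
#' @param min_support,delta,peak_fraction see [classify_sample()] and
#'   [length_profile()].
#' @return A `locus_summary` list: `hotspot_name`, `n_mut`, `n_wt`,
#'   `n_unresolved`, `maf`, `freq_bin`, `mut_profile`, `wt_profile`,
#'   `description`. Profiles are `NULL` when an allele has no fragments
#'   (MAF can still be defined); `maf` and `freq_bin` are `NA` when no
#'   fragment was typed.
#' @export
summarize_locus <- function(typed, hotspot, min_support = 5L, delta = 3,
                            peak_fraction = 0.8) {
  hotspot <- as_single_hotspot(hotspot)
  n_mut <- sum(typed$allele == "mutant")
  n_wt <- sum(typed$allele == "wild")
  n_un <- sum(typed$allele == "unresolved")
  maf <- if (n_mut + n_wt > 0) compute_maf(n_mut, n_wt) else NA_real_
  mut_profile <- if (n_mut > 0)
    length_profile(typed$length[typed$allele == "mutant"], peak_fraction)
  else NULL
  wt_profile <- if (n_wt > 0)
    length_profile(typed$length[typed$allele == "wild"], peak_fraction)
  else NULL
  description <- if (is.null(wt_profile)) {
    "Insufficient"
  } else if (is.null(mut_profile)) {
    if (n_mut < min_support) "Insufficient" else "Normal"
  } else {
    classify_sample(mut_profile, wt_profile, min_support, delta)
  }
  structure(list(
    hotspot_name = hotspot$name, n_mut = n_mut, n_wt = n_wt,
    n_unresolved = n_un, maf = maf,
    freq_bin = if (is.na(maf)) NA_character_
               else as.character(bin_frequency(maf)),
    mut_profile = mut_profile, wt_profile = wt_profile,
    description = description
  ), class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  cat(sprintf("%s: MAF %.4f (%s), %d mut / %d wt / %d unresolved, %s\n",
              x$hotspot_name, x$maf, x$freq_bin, x$n_mut, x$n_wt,
              x$n_unresolved, x$description))
  invisible(x)
}

#' Analyze aligned reads over a hotspot panel
#'
#' The core pipeline: for each panel hotspot, extract covering read pairs
#' from the alignment file, recover fragment lengths from TLEN, type each
#' fragment's allele, and summarize. Hotspots where no fragment survives
#' extraction are skipped (reported in the result's `skipped` element).
#'
#' @param path SAM/BAM file.
#' @param panel a `hotspot_panel`.
#' @param min_mapq,require_proper_pair,min_base_quality see
#'   [extract_pairs_at_hotspot()].
#' @param min_support,delta,peak_fraction see [summarize_locus()].
#' @return A list with `summaries` (named list of `locus_summary`), `typed`
#'   (named list of typed-fragment data.frames), `tallies` (named list of
#'   filter tallies), `skipped` (character vector of hotspot names with no
#'   observations).
#' @export
analyze_sam <- function(path, panel, min_mapq = 20L,
                        require_proper_pair = TRUE, min_base_quality = 0L,
                        min_support = 5L, delta = 3, peak_fraction = 0.8) {
  panel <- validate_panel(panel)
  summaries <- list()
  typed_all <- list()
  tallies <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(panel))) {
    hs <- panel[i, ]
    ext <- extract_pairs_at_hotspot(path, hs, min_mapq = min_mapq,
                                    require_proper_pair = require_proper_pair,
                                    min_base_quality = min_base_quality)
    tallies[[hs$name]] <- ext$tallies
    if (nrow(ext$observations) == 0L) {
      skipped <- c(skipped, hs$name)
      next
    }
    typed <- type_fragments(ext$observations, hs)
    typed_all[[hs$name]] <- typed
    summaries[[hs$name]] <- summarize_locus(typed, hs, min_support, delta,
                                            peak_fraction)
  }
  list(summaries = summaries, typed = typed_all, tallies = tallies,
       skipped = skipped)
}

#' Per-sample report table
#'
#' Flattens locus summaries into the standard per-sample report: one row per
#' hotspot with the mutation type, NGS and ddPCR percentages, the
#' Short/Long/Normal/Other description, per-allele modal peak(s)
#' (slash-separated when multiple) and medians — eight content columns.
#' Percentages are reported to two decimal places.
#'
#' @param summaries list of `locus_summary` objects.
#' @param ddpcr_pct optional named numeric vector of ddPCR percentages,
#'   indexed by hotspot name.
#' @return A data.frame with columns `mutation_type`, `ngs_pct`, `ddpcr_pct`,
#'   `description`, `mutation_peak`, `wild_peak`, `mutation_median`,
#'   `wild_median`.
#' @export
summary_table <- function(summaries, ddpcr_pct = NULL) {
  rows <- lapply(summaries, function(s) {
    peaks <- function(p) if (is.null(p)) NA_character_
      else paste(p$modes, collapse = "/")
    med <- function(p) if (is.null(p)) NA_real_ else p$median
    data.frame(
      mutation_type = s$hotspot_name,
      ngs_pct = round(100 * s$maf, 2),
      ddpcr_pct = if (!is.null(ddpcr_pct) && s$hotspot_name %in% names(ddpcr_pct))
        round(ddpcr_pct[[s$hotspot_name]], 2) else NA_real_,
      description = s$description,
      mutation_peak = peaks(s$mut_profile),
      wild_peak = peaks(s$wt_profile),
      mutation_median = med(s$mut_profile),
      wild_median = med(s$wt_profile),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a length-profile histogram as TSV
#'
#' @param profile a `length_profile`.
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, header_lines = character(0)) {
  lines <- c(header_lines, "#length\tcount",
             paste(profile$histogram$length, profile$histogram$count,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
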