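# Representation classification and species-level rollups. Thresholds are
# strict ("<8%", "<5%") and the classes nest: a map with 0% is also counted
# in every below-threshold tally. The 8 default documents its provenance:
# the global KBA network covers 8.01% of Earth's terrestrial surface, so a
# randomly placed species would expect ~8% of its habitat inside sites.

#' Classify percent-in-sites into representation classes
#'
#' Strict less-than semantics at both thresholds: `no_overlap` at exactly
#' 0%, `very_under` below the lower threshold, `under` below the upper
#' threshold, `adequate` otherwise. The labels are the *finest* class; use
#' [count_below()] for the nested tallies (every `no_overlap` map is also
#' below both thresholds).
#'
#' @param pct Numeric vector of percentages in [0, 100]; `NA` passes through.
#' @param thresholds Ascending pair `c(very_under, under)`, default `c(5, 8)`.
#' @return Factor with levels `no_overlap`, `very_under`, `under`,
#'   `adequate`.
#' @export
classify_overlap <- function(pct, thresholds = c(5, 8)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  bad <- !is.na(pct) & (pct < 0 | pct > 100)
  if (any(bad)) stop("percentages must lie in [0, 100]", call. = FALSE)
  lv <- c("no_overlap", "very_under", "under", "adequate")
  out <- rep(NA_character_, length(pct))
  out[!is.na(pct)] <- "adequate"
  out[!is.na(pct) & pct < thresholds[2]] <- "under"
  out[!is.na(pct) & pct < thresholds[1]] <- "very_under"
  out[!is.na(pct) & pct == 0] <- "no_overlap"
  factor(out, levels = lv)
}

#' Nested below-threshold count
#'
#' `sum(pct < threshold)` over non-missing values — includes zero-overlap
#' maps, so counts at increasing thresholds nest.
#'
#' @param pct Percentages.
#' @param threshold Strict upper bound.
#' @export
count_below <- function(pct, threshold) sum(pct < threshold, na.rm = TRUE)

#' Roll per-season maps up to species level
#'
#' A species counts as under-represented if *any* of its seasonal ranges
#' falls below the threshold. Flagged species are partitioned into the four
#' seasonal patterns: `resident`, `both_seasons_under`,
#' `breeding_only_under`, `nonbreeding_only_under`.
#'
#' @param summary A `map_summary` from [summarize_maps()].
#' @param threshold Strict percentage threshold (default 5, the
#'   very-under-represented level at which seasonal patterns are usually
#'   reported).
#' @return Data frame with one row per species: `species_id`,
#'   `pct_resident`, `pct_breeding`, `pct_nonbreeding`, `min_pct`,
#'   `flagged`, `pattern` (NA for unflagged species).
#' @export
rollup_species <- function(summary, threshold = 5) {
  s <- summary[summary$usable, , drop = FALSE]
  if (anyDuplicated(s[, c("species_id", "season")])) {
    stop("duplicate (species, season) map", call. = FALSE)
  }
  sp <- unique(s$species_id)
  get_pct <- function(id, season) {
    v <- s$pct_in_sites[s$species_id == id & s$season == season]
    if (length(v)) v else NA_real_
  }
  rows <- lapply(sp, function(id) {
    pr <- get_pct(id, "resident")
    pb <- get_pct(id, "breeding")
    pn <- get_pct(id, "nonbreeding")
    pcts <- c(pr, pb, pn)
    min_pct <- min(pcts, na.rm = TRUE)
    flagged <- any(pcts < threshold, na.rm = TRUE)
    pattern <- if (!flagged) NA_character_
      else if (!is.na(pr)) "resident"
      else {
        bu <- isTRUE(pb < threshold); nu <- isTRUE(pn < threshold)
        if (bu && nu) "both_seasons_under"
        else if (bu) "breeding_only_under"
        else "nonbreeding_only_under"
      }
    data.frame(species_id = id, pct_resident = pr, pct_breeding = pb,
               pct_nonbreeding = pn, min_pct = min_pct, flagged = flagged,
               pattern = pattern, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare mean representation between trigger and non-trigger species
#'
#' Unweighted arithmetic mean of per-map percentages in each group (species
#' with at least one site identified for them vs the rest) and their
#' difference. Empty groups yield `NA` means.
#'
#' @param summary A `map_summary`.
#' @param species Species attribute table with `species_id` and a logical
#'   `trigger` column (or a logical vector aligned with `summary` rows).
#' @return List with the two group means (`mean_trigger`,
#'   `mean_non_trigger`), their difference in percentage points
#'   (`difference`), and per-group map counts.
#' @export
compare_trigger_groups <- function(summary, species) {
  s <- summary[summary$usable, , drop = FALSE]
  trig <- if (is.logical(species)) {
    species[summary$usable]
  } else {
    species$trigger[match(s$species_id, species$species_id)]
  }
  grp_mean <- function(g) if (any(g)) mean(s$pct_in_sites[g]) else NA_real_
  m_t <- grp_mean(trig %in% TRUE)
  m_n <- grp_mean(trig %in% FALSE)
  list(mean_trigger = m_t, mean_non_trigger = m_n,
       difference = m_t - m_n,
       n_trigger = sum(trig %in% TRUE), n_non_trigger = sum(trig %in% FALSE))
}

#' Cross-check the worst-covered maps against protected areas
#'
#' Restricts to the gap subset — maps with no site overlap at all, plus
#' threatened species' maps below the very-under threshold — and reports
#' which of them also have zero protected-area coverage: the species with
#' no safety net anywhere.
#'
#' @param summary A `map_summary` that includes `pct_protected` (i.e.
#'   [summarize_maps()] was given a protected-area union).
#' @param species Attribute table with `species_id` and `threatened`.
#' @param very_under Strict threshold for the threatened subset (default 5).
#' @return Data frame of gap-subset maps with `pct_protected == 0`;
#'   attributes `subset_n` (subset size) and `zero_n`.
#' @export
pa_crosscheck <- function(summary, species, very_under = 5) {
  if (is.null(summary$pct_protected)) {
    stop("`summary` lacks protected-area percentages; pass `pa_union` to summarize_maps()",
         call. = FALSE)
  }
  s <- summary[summary$usable, , drop = FALSE]
  thr <- species$threatened[match(s$species_id, species$species_id)]
  subset <- s$pct_in_sites == 0 | (thr %in% TRUE & s$pct_in_sites < very_under)
  sub <- s[subset, , drop = FALSE]
  out <- sub[sub$pct_protected == 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, subset_n = nrow(sub), zero_n = nrow(out))
}
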