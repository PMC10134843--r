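#' Above-mean peak profile of one abundance series
#'
#' A day belongs to a peak when the vOTU's abundance on that day is
#' strictly greater than the mean of its own series over the days with
#' data. A constant series therefore has no peak days ("flat").
#'
#' @param series numeric abundance values (e.g. TPM), one per sampled day.
#' @param days integer Julian days, strictly increasing, same length as
#'   `series`.
#' @return A list with `days` and logical `above_mean`.
#' @export
peak_profile <- function(series, days) {
  keep <- !is.na(series)
  if (sum(keep) < 2L) stop("need at least two non-missing days")
  series <- series[keep]
  days <- days[keep]
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  list(days = days, above_mean = series > mean(series))
}

# day groups of the peak typology
.peak_groups <- list(g1 = c(165L, 181L), g2 = c(193L, 208L),
                     g3 = c(243L, 271L), g4 = c(165L, 271L))

#' Classify a peak profile into the single/wide/several typology
#'
#' Labels an above-mean pattern over the six sampled Julian days
#' (165, 181, 193, 208, 243, 271 by default):
#'
#' * `flat` — no above-mean day (constant series);
#' * `single1`..`single3` — exactly one above-mean day, falling in
#'   day group G1 = \{165, 181\}, G2 = \{193, 208\} or G3 = \{243, 271\};
#' * `single4` — exactly the two-day pattern \{165, 271\} (one peak at
#'   each end of the series);
#' * `wide1`..`wide3` — one contiguous run of 2 or 3 consecutive sampled
#'   days, subtyped by the group containing the first day of the run
#'   (G1, then G2, then G3);
#' * `several` — everything else (non-contiguous patterns other than
#'   \{165, 271\}, and runs of 4 or more days).
#'
#' Adjacency is defined on consecutive *sampled* days, not calendar gaps.
#'
#' @param profile result of [peak_profile()], or a list with `days` and
#'   logical `above_mean`.
#' @return A single label string.
#' @examples
#' classify_peak(list(days = c(165, 181, 193, 208, 243, 271),
#'                    above_mean = c(F, F, F, F, T, F))) # "single3"
#' @export
classify_peak <- function(profile) {
  am <- profile$above_mean
  days <- profile$days
  stopifnot(length(am) == length(days))
  idx <- which(am)
  n <- length(idx)
  if (n == 0L) return("flat")
  peak_days <- days[idx]
  if (setequal(peak_days, .peak_groups$g4) && n == 2L) return("single4")
  if (n == 1L) {
    for (k in 1:3) {
      if (peak_days %in% .peak_groups[[k]]) return(paste0("single", k))
    }
    return("several") # day outside the canonical groups
  }
  contiguous <- all(diff(idx) == 1L)
  if (contiguous && n %in% 2:3) {
    first <- peak_days[1L]
    for (k in 1:3) {
      if (first %in% .peak_groups[[k]]) return(paste0("wide", k))
    }
  }
  "several"
}

#' Peak classification of every vOTU at every station
#'
#' Computes the per-station above-mean profile of each vOTU and its peak
#' class. Stations with fewer than two sampled days are rejected.
#'
#' @param ab TPM matrix, vOTUs in rows, samples in columns.
#' @param samples data.frame with columns `sample`, `station`,
#'   `julian_day`; every column of `ab` must appear once.
#' @param pooled if TRUE, classify over all samples pooled (averaging
#'   replicate stations per day) instead of per station.
#' @return data.frame `votu_id`, `station` (`"pooled"` in pooled mode),
#'   `label`, `pattern` (above-mean days as a `;`-joined string, `""` for
#'   flat).
#' @export
peak_classes <- function(ab, samples, pooled = FALSE) {
  if (!all(colnames(ab) %in% samples$sample))
    stop("samples table must describe every column of ab")
  samples <- samples[match(colnames(ab), samples$sample), ]
  groups <- if (pooled) list(pooled = seq_len(ncol(ab)))
            else split(seq_len(ncol(ab)), samples$station)
  out <- lapply(names(groups), function(st) {
    cols <- groups[[st]]
    day <- samples$julian_day[cols]
    agg <- rowsum(t(ab[, cols, drop = FALSE]), day) # day x votu, sums reps
    agg <- agg / as.vector(table(day)[rownames(agg)])
    days <- as.integer(rownames(agg))
    o <- order(days)
    days <- days[o]
    agg <- agg[o, , drop = FALSE]
    labs <- character(ncol(agg))
    pats <- character(ncol(agg))
    for (i in seq_len(ncol(agg))) {
      pr <- peak_profile(agg[, i], days)
      labs[i] <- classify_peak(pr)
      pats[i] <- paste(pr$days[pr$above_mean], collapse = ";")
    }
    data.frame(votu_id = colnames(agg), station = st, label = labs,
               pattern = pats, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-station peak-class composition
#'
#' @param classes data.frame from [peak_classes()].
#' @param labels optional label universe for zero-filled rows.
#' @return data.frame `station`, `label`, `n`, `percent`; percentages sum
#'   to 100 within each station (flat is reported as its own row).
#' @export
class_composition <- function(classes,
                              labels = c(paste0("single", 1:4),
                                         paste0("wide", 1:4),
                                         "several", "flat")) {
  if (nrow(classes) == 0L) stop("no classified vOTUs")
  stations <- unique(classes$station)
  out <- lapply(stations, function(st) {
    sub <- classes[classes$station == st, ]
    if (nrow(sub) == 0L) stop("station without classified vOTUs: ", st)
    tab <- table(factor(sub$label, levels = labels))
    data.frame(station = st, label = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / nrow(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
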