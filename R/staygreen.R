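# Thermal-time-corrected relative stay-green scoring: accumulated
# temperature, stage assignment, RSS/RSGS algebra and the flowering-class
# correction factor.

#' Post-anthesis accumulated temperature
#'
#' Sum of daily mean temperatures over the days after anthesis up to and
#' including the target day (exclusive of the anthesis day itself).
#'
#' @param weather An `sg_weather` (or data frame with `date`, `tmean`).
#' @param anthesis Anthesis date.
#' @param target Target date (`anthesis <= target`); both must lie within
#'   the weather span.
#' @return Accumulated temperature, degrees C day.
#' @export
accumulated_temperature <- function(weather, anthesis, target) {
  anthesis <- as.Date(anthesis)
  target <- as.Date(target)
  sg_assert(anthesis <= target, "anthesis must not be after target")
  span <- range(weather$date)
  if (anthesis < span[1] || target > span[2]) {
    sg_stop("date outside the weather span", "sg_missing_weather")
  }
  sum(weather$tmean[weather$date > anthesis & weather$date <= target])
}

#' Thermal context of a trial
#'
#' Bundles the weather series, per-accession anthesis dates and flowering
#' classes (EF/MF/LF). When classes are not supplied they are assigned by a
#' tercile split of the anthesis dates (earliest third = EF).
#'
#' @param weather An `sg_weather`.
#' @param anthesis_dates Named `Date` vector, one per accession.
#' @param flowering Optional named character vector of classes in
#'   `{EF, MF, LF}`.
#' @return Object of class `sg_thermal`.
#' @export
thermal_context <- function(weather, anthesis_dates, flowering = NULL) {
  anthesis_dates <- as.Date(anthesis_dates)
  sg_assert(!is.null(names(anthesis_dates)),
            "anthesis_dates must be named by accession")
  span <- range(weather$date)
  sg_assert(all(anthesis_dates >= span[1] & anthesis_dates <= span[2]),
            "anthesis dates must lie within the weather span",
            "sg_missing_weather")
  n <- length(anthesis_dates)
  if (is.null(flowering)) {
    rk <- rank(as.numeric(anthesis_dates), ties.method = "first")
    flowering <- c("EF", "MF", "LF")[ceiling(3 * rk / n)]
    names(flowering) <- names(anthesis_dates)
  } else {
    flowering <- flowering[names(anthesis_dates)]
    sg_assert(all(flowering %in% c("EF", "MF", "LF")),
              "flowering classes must be EF, MF or LF")
  }
  structure(list(weather = weather, anthesis = anthesis_dates,
                 flowering = flowering),
            class = "sg_thermal")
}

# AT of each flight date for one accession; dates at or before anthesis
# count 0 (canopy still at the anthesis reference).
at_of_dates <- function(thermal, acc, dates) {
  a <- thermal$anthesis[[acc]]
  vapply(dates, function(d) {
    if (d <= a) 0 else accumulated_temperature(thermal$weather, a, d)
  }, 0)
}

#' Map stages to flight dates on the thermal-time axis
#'
#' For each accession and senescence stage, picks the flight whose
#' accumulated temperature is nearest the stage's AT boundary (ties broken
#' towards the earlier date). Stages with no flight within `tol` of the
#' boundary are left unresolved (missing) with a warning. The class-level AT
#' actually attained per stage feeds the flowering correction factor
#' `k = AT_MF / AT_class` (so `k = 1` for MF at every stage).
#'
#' @param traj An `sg_traj`.
#' @param thermal An `sg_thermal` covering the trajectory's plots.
#' @param boundaries Named increasing AT boundaries, degrees C day
#'   (default `c(S1 = 300, S2 = 400, S3 = 550, S4 = 700)`).
#' @param tol Maximum |AT - boundary| for a flight to resolve a stage,
#'   degrees C day.
#' @return Object of class `sg_stages`: per-accession stage flights and AT,
#'   class-level AT and the `k` correction matrix.
#' @export
assign_stages <- function(traj, thermal,
                          boundaries = c(S1 = 300, S2 = 400, S3 = 550,
                                         S4 = 700),
                          tol = 60) {
  sg_assert(inherits(traj, "sg_traj"), "traj must be an sg_traj")
  sg_assert(inherits(thermal, "sg_thermal"), "thermal must be an sg_thermal")
  sg_assert(all(diff(boundaries) > 0),
            "stage boundaries must be strictly increasing")
  acc <- dimnames(traj$values)[[1]]
  sg_assert(all(acc %in% names(thermal$anthesis)),
            "thermal context is missing accessions present in the trajectory",
            "sg_missing_data")
  n_stage <- length(boundaries)
  stage_names <- names(boundaries) %||% paste0("S", seq_len(n_stage))
  stage_flight <- matrix(NA_integer_, length(acc), n_stage,
                         dimnames = list(acc, stage_names))
  stage_at <- matrix(NA_real_, length(acc), n_stage,
                     dimnames = list(acc, stage_names))
  for (a in acc) {
    at <- at_of_dates(thermal, a, traj$dates)
    for (s in seq_len(n_stage)) {
      d <- abs(at - boundaries[s])
      j <- which.min(d)          # first minimum = earlier date on ties
      if (d[j] <= tol) {
        stage_flight[a, s] <- j
        stage_at[a, s] <- at[j]
      }
    }
  }
  n_miss <- sum(is.na(stage_flight))
  if (n_miss > 0) {
    warning(sprintf(
      "%d accession-stage combination(s) unresolved (no flight within %g degC day of the boundary)",
      n_miss, tol))
  }
  classes <- c("EF", "MF", "LF")
  fl <- thermal$flowering[acc]
  class_at <- matrix(NA_real_, 3, n_stage,
                     dimnames = list(classes, stage_names))
  for (cl in classes) {
    rows <- which(fl == cl)
    if (length(rows)) {
      class_at[cl, ] <- colMeans(stage_at[rows, , drop = FALSE], na.rm = TRUE)
    }
  }
  sg_assert(any(fl == "MF"),
            "no MF accessions: the correction factor is undefined",
            "sg_missing_data")
  k <- sweep(1 / class_at, 2, class_at["MF", ], `*`)
  k["MF", ] <- 1   # exact by definition
  structure(list(stage_flight = stage_flight, stage_at = stage_at,
                 class_at = class_at, k = k, boundaries = boundaries,
                 tol = tol, flowering = fl),
            class = "sg_stages")
}

#' Relative senescence score
#'
#' `RSS = (Index_anthesis - Index_Si) / Index_anthesis * 100`. The anthesis
#' value is the maximum stay-green reference; an index above it yields a
#' negative RSS, which is retained (and flagged downstream), never clamped,
#' so that `RSS + RSGS = 100` holds exactly.
#'
#' @param index_anthesis Index value at anthesis (> 0).
#' @param index_si Index value at the stage.
#' @return RSS on the 0-100 scale (vectorized).
#' @export
rss <- function(index_anthesis, index_si) {
  if (any(is.finite(index_anthesis) & index_anthesis <= 0)) {
    sg_stop("index_anthesis must be positive", "sg_undefined_baseline")
  }
  (index_anthesis - index_si) / index_anthesis * 100
}

#' Relative stay-green score
#'
#' `RSGS = 100 - RSS`; the anthesis reference scores exactly 100.
#'
#' @param rss_value RSS value(s).
#' @return RSGS value(s).
#' @export
rsgs <- function(rss_value) 100 - rss_value

#' Flowering-class correction factor
#'
#' `k_i` is the ratio of the AT of MF samples at stage Si to the AT of the
#' EF or LF samples at the same stage.
#'
#' @param at_mf_si AT of the MF class at stage Si (> 0).
#' @param at_group_si AT of the class being corrected at stage Si (> 0).
#' @return Correction factor `k_i` (vectorized).
#' @export
correction_factor <- function(at_mf_si, at_group_si) {
  if (any(at_mf_si <= 0) || any(at_group_si <= 0)) {
    sg_stop("accumulated temperatures must be positive", "sg_invalid_at")
  }
  at_mf_si / at_group_si
}

#' Flowering-corrected relative stay-green score
#'
#' `RSGS_corrected = 100 - k_i * RSS`; with `k = 1` (MF samples) this equals
#' the uncorrected RSGS.
#'
#' @param rss_value RSS value(s).
#' @param k_i Correction factor(s) (> 0).
#' @return Corrected RSGS (vectorized).
#' @export
corrected_rsgs <- function(rss_value, k_i) {
  sg_assert(all(k_i > 0), "k_i must be positive")
  100 - k_i * rss_value
}

#' Build the full stage-wise RSGS table
#'
#' Composes the RSS/RSGS algebra with the stage assignment: one corrected
#' stay-green score per accession, spectral index and stage. MF accessions
#' keep the uncorrected score (their `k` is 1 by definition); EF/LF scores
#' are corrected by their class `k`. Unresolved stages propagate as missing
#' traits.
#'
#' @param traj An `sg_traj`.
#' @param thermal An `sg_thermal`.
#' @param stages An `sg_stages` from [assign_stages()] (computed here when
#'   omitted).
#' @param ... Passed to [assign_stages()] when `stages` is missing.
#' @return Object of class `sg_rsgs`: long data frame with columns
#'   `accession, index, stage, trait, flight_date, at, k, rss, rsgs, sg,
#'   negative_rss`, where `sg` is the corrected RSGS (the GWAS phenotype).
#' @export
build_rsgs_table <- function(traj, thermal, stages = NULL, ...) {
  sg_assert(inherits(traj, "sg_traj"), "traj must be an sg_traj")
  if (is.null(stages)) stages <- assign_stages(traj, thermal, ...)
  acc <- dimnames(traj$values)[[1]]
  idx_names <- dimnames(traj$values)[[3]]
  stage_names <- colnames(stages$stage_flight)
  fl <- stages$flowering
  rows <- vector("list", length(idx_names) * length(stage_names))
  r_i <- 0L
  for (ix in idx_names) {
    ia <- traj$anthesis[, ix]
    for (s in seq_along(stage_names)) {
      j <- stages$stage_flight[, s]
      is_val <- rep(NA_real_, length(acc))
      ok <- !is.na(j)
      is_val[ok] <- traj$values[cbind(which(ok), j[ok],
                                      match(ix, idx_names))]
      rss_v <- rss(ia, is_val)
      k_v <- stages$k[cbind(match(fl, rownames(stages$k)),
                            rep(s, length(acc)))]
      r_i <- r_i + 1L
      rows[[r_i]] <- data.frame(
        accession = acc, index = ix, stage = stage_names[s],
        trait = sprintf("SG_%s%d", toupper(ix), s),
        flight_date = traj$dates[ifelse(ok, j, NA)],
        at = stages$stage_at[, s], k = k_v,
        rss = rss_v, rsgs = rsgs(rss_v),
        sg = 100 - k_v * rss_v,
        negative_rss = !is.na(rss_v) & rss_v < 0,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sg_rsgs", "data.frame")
  out
}

#' Pivot an RSGS table to an accession-by-trait matrix
#'
#' @param tbl An `sg_rsgs` table.
#' @param value Column to spread (default `"sg"`, the corrected score).
#' @return Numeric matrix, accessions in rows, `SG_<INDEX><stage>` traits in
#'   columns.
#' @export
rsgs_wide <- function(tbl, value = "sg") {
  sg_assert(inherits(tbl, "sg_rsgs"), "tbl must be an sg_rsgs")
  acc <- unique(tbl$accession)
  traits <- unique(tbl$trait)
  out <- matrix(NA_real_, length(acc), length(traits),
                dimnames = list(acc, traits))
  out[cbind(match(tbl$accession, acc), match(tbl$trait, traits))] <-
    tbl[[value]]
  out
}
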