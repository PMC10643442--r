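# Questionnaire and accelerometer sleep-trait encoders.

ukb_maps <- list(
  chronotype = c("Definitely an 'evening' person" = 1,
                 "More an 'evening' than a 'morning' person" = 2,
                 "Do not know" = 3,
                 "More a 'morning' than 'evening' person" = 4,
                 "Definitely a 'morning' person" = 5),
  ease_of_waking = c("Not at all easy" = 1, "Not very easy" = 2,
                     "Fairly easy" = 3, "Very easy" = 4),
  insomnia = c("Never/rarely" = 1, "Sometimes" = 2, "Usually" = 3),
  snoring = c("No" = 0, "Yes" = 1)
)

map_responses <- function(x, map, missing_values, field,
                          extra_missing = character(0)) {
  x <- as.character(x)
  known <- c(names(map), missing_values, extra_missing, NA)
  bad <- unique(x[!(x %in% known) & !is.na(x)])
  if (length(bad)) {
    stop_schema("unknown response value(s) for ", field, ": ",
                paste(sQuote(bad), collapse = ", "))
  }
  out <- unname(map[x])
  out[x %in% c(missing_values, extra_missing)] <- NA
  out
}

#' Encode UK-dialect questionnaire sleep traits
#'
#' Applies the documented category maps: chronotype is a 5-level ordinal
#' (1 = definite evening ... 5 = definite morning) in which "Do not know" is
#' treated as the intermediate category 3; ease of waking is a 4-level
#' ordinal; insomnia symptom frequency a 3-level ordinal; snoring binary;
#' sleep duration is reported in whole hours.  "Prefer not to say" (and
#' "Do not know" outside chronotype) is missing.  Two derived binaries are
#' added: `chronotype_binary` (morning = 1 vs evening = 0, "Do not know"
#' excluded) and `insomnia_binary` (usually = 1 vs never/sometimes = 0).
#'
#' @param raw data.frame with `individual_id` and any of `chronotype`,
#'   `ease_of_waking`, `sleep_duration`, `insomnia`, `snoring` holding the
#'   documented response strings (sleep duration numeric or string hours).
#' @return a data.frame of encoded traits with attribute `dialect = "ukb"`.
#' @export
#' @examples
#' encode_ukb_traits(data.frame(individual_id = "a",
#'                              chronotype = "Do not know"))
encode_ukb_traits <- function(raw) {
  require_columns(raw, "individual_id", "raw")
  pnts <- "Prefer not to say"
  out <- data.frame(individual_id = raw$individual_id,
                    stringsAsFactors = FALSE)
  if ("chronotype" %in% names(raw)) {
    out$chronotype <- map_responses(raw$chronotype, ukb_maps$chronotype,
                                    pnts, "chronotype")
    out$chronotype_binary <- ifelse(out$chronotype %in% c(4, 5), 1,
                                    ifelse(out$chronotype %in% c(1, 2), 0,
                                           NA))
  }
  if ("ease_of_waking" %in% names(raw)) {
    out$ease_of_waking <- map_responses(raw$ease_of_waking,
                                        ukb_maps$ease_of_waking,
                                        c(pnts, "Do not know"),
                                        "ease_of_waking")
  }
  if ("sleep_duration" %in% names(raw)) {
    x <- as.character(raw$sleep_duration)
    x[x %in% c(pnts, "Do not know")] <- NA
    suppressWarnings(num <- as.numeric(x))
    bad <- unique(x[!is.na(x) & is.na(num)])
    if (length(bad)) {
      stop_schema("unknown response value(s) for sleep_duration: ",
                  paste(sQuote(bad), collapse = ", "))
    }
    out$sleep_duration_h <- num
  }
  if ("insomnia" %in% names(raw)) {
    out$insomnia <- map_responses(raw$insomnia, ukb_maps$insomnia,
                                  c(pnts, "Do not know"), "insomnia")
    out$insomnia_binary <- ifelse(is.na(out$insomnia), NA,
                                  as.numeric(out$insomnia == 3))
  }
  if ("snoring" %in% names(raw)) {
    out$snoring <- map_responses(raw$snoring, ukb_maps$snoring,
                                 c(pnts, "Do not know"), "snoring")
  }
  attr(out, "dialect") <- "ukb"
  out
}

#' Decode UK-dialect ordinal codes back to response strings
#'
#' Inverse of [encode_ukb_traits()] on non-missing documented responses
#' (the derived binaries are not decoded).
#'
#' @param encoded output of [encode_ukb_traits()].
#' @return data.frame of response strings.
#' @export
decode_ukb_traits <- function(encoded) {
  out <- data.frame(individual_id = encoded$individual_id,
                    stringsAsFactors = FALSE)
  for (field in c("chronotype", "ease_of_waking", "insomnia", "snoring")) {
    if (field %in% names(encoded)) {
      map <- ukb_maps[[field]]
      out[[field]] <- names(map)[match(encoded[[field]], map)]
    }
  }
  if ("sleep_duration_h" %in% names(encoded)) {
    out$sleep_duration <- encoded$sleep_duration_h
  }
  out
}

#' Encode 23andMe-dialect questionnaire sleep traits
#'
#' Builds the binary morningness variable ("Morning person" = 1 vs "Night
#' person" = 0; "It depends", "I'm not sure" and "Neither" are missing), a
#' binary insomnia-diagnosis variable ("Yes" vs "No", "I'm not sure"
#' missing), self-snoring ("Yes" vs "No", "I'm not sure" missing) and sleep
#' hours with extreme responses below 3 h or above 12 h set missing.
#'
#' @param raw data.frame with `individual_id` and any of `morning_person`,
#'   `insomnia`, `sleep_duration`, `snoring`.
#' @return a data.frame of encoded traits with attribute
#'   `dialect = "23andme"`.
#' @export
encode_23andme_traits <- function(raw) {
  require_columns(raw, "individual_id", "raw")
  out <- data.frame(individual_id = raw$individual_id,
                    stringsAsFactors = FALSE)
  if ("morning_person" %in% names(raw)) {
    out$morning_person <- map_responses(
      raw$morning_person, c("Night person" = 0, "Morning person" = 1),
      c("It depends", "I'm not sure", "Neither"), "morning_person")
  }
  if ("insomnia" %in% names(raw)) {
    out$insomnia_diagnosis <- map_responses(
      raw$insomnia, c("No" = 0, "Yes" = 1), "I'm not sure", "insomnia")
  }
  if ("sleep_duration" %in% names(raw)) {
    x <- suppressWarnings(as.numeric(as.character(raw$sleep_duration)))
    x[!is.na(x) & (x < 3 | x > 12)] <- NA
    out$sleep_duration_h <- x
  }
  if ("snoring" %in% names(raw)) {
    out$snoring <- map_responses(raw$snoring, c("No" = 0, "Yes" = 1),
                                 "I'm not sure", "snoring")
  }
  attr(out, "dialect") <- "23andme"
  out
}

#' Quality-control filter for accelerometer sleep records
#'
#' Drops records carrying any device QC flag (data problem, poor wear time,
#' poor calibration, calibration requiring other data), then computes, over
#' the flag-clean records, the upper outlier fence Q3 + 1.5 x IQR for each
#' recording-error variable (`n_recording_errors`, `n_interrupted_periods`,
#' `interrupted_duration`) and drops records exceeding their fence.
#' Quartiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`).
#'
#' @param records data.frame with `individual_id`, logical/0-1 flag columns
#'   `qc_data_problem`, `qc_poor_wear`, `qc_poor_calibration`,
#'   `qc_calibration_other_data`, and the error-count columns above (any
#'   subset of the error-count columns may be present).
#' @return list with `records` (retained rows) and `drop_log`
#'   (`individual_id`, `rule`); a warning is raised (not an error) when all
#'   records are dropped.
#' @export
accelerometer_qc <- function(records) {
  flags <- c("qc_data_problem", "qc_poor_wear", "qc_poor_calibration",
             "qc_calibration_other_data")
  require_columns(records, c("individual_id", flags), "records")
  err_vars <- intersect(c("n_recording_errors", "n_interrupted_periods",
                          "interrupted_duration"), names(records))
  drop_log <- data.frame(individual_id = character(0), rule = character(0),
                         stringsAsFactors = FALSE)
  flagged <- rep(FALSE, nrow(records))
  for (f in flags) {
    hit <- records[[f]] %in% c(TRUE, 1)
    if (any(hit)) {
      drop_log <- rbind(drop_log,
                        data.frame(individual_id =
                                     records$individual_id[hit],
                                   rule = f, stringsAsFactors = FALSE))
    }
    flagged <- flagged | hit
  }
  clean <- records[!flagged, , drop = FALSE]
  outlier <- rep(FALSE, nrow(clean))
  for (v in err_vars) {
    q <- stats::quantile(clean[[v]], c(0.25, 0.75), na.rm = TRUE, type = 7)
    fence <- q[[2]] + 1.5 * (q[[2]] - q[[1]])
    hit <- !is.na(clean[[v]]) & clean[[v]] > fence
    if (any(hit)) {
      drop_log <- rbind(drop_log,
                        data.frame(individual_id = clean$individual_id[hit],
                                   rule = paste0(v, "_outlier"),
                                   stringsAsFactors = FALSE))
    }
    outlier <- outlier | hit
  }
  retained <- clean[!outlier, , drop = FALSE]
  if (nrow(retained) == 0L && nrow(records) > 0L) {
    warning("accelerometer_qc dropped every record")
  }
  list(records = retained, drop_log = drop_log)
}

#' Render an L5 timing as a clock time
#'
#' L5 timing (midpoint of the least-active five hours) is stored as hours
#' elapsed from the previous midnight, on a linear 12-36 h axis so that
#' cross-person arithmetic never wraps.  This converts a value to a 12-hour
#' clock reading: 27.3 renders as 3:18 am.
#'
#' @param x numeric vector of hours in `[12, 36)`.
#' @return data.frame with `hour` (1-12), `minute`, `period` ("am"/"pm")
#'   and a formatted `label`.
#' @export
#' @examples
#' l5_to_clock(27.3)
l5_to_clock <- function(x) {
  if (any(is.na(x)) || any(x < 12 | x >= 36)) {
    stop_param("L5 timing must lie in [12, 36)")
  }
  h24 <- ifelse(x >= 24, x - 24, x)
  total_min <- round(h24 * 60)
  hh <- (total_min %/% 60) %% 24
  mm <- total_min %% 60
  period <- ifelse(hh < 12, "am", "pm")
  hour12 <- hh %% 12
  hour12[hour12 == 0] <- 12
  data.frame(hour = hour12, minute = mm, period = period,
             label = sprintf("%d:%02d %s", hour12, mm, period),
             stringsAsFactors = FALSE)
}

#' Standardise a trait vector to mean 0, SD 1
#'
#' Uses the sample standard deviation (n-1 denominator) over non-missing
#' entries; intended to be applied on the analysis sample after pairing and
#' complete-case restriction so that regression slopes read as SD per SD.
#'
#' @param x numeric vector with at least two distinct non-missing values.
#' @return standardised vector (missing entries preserved).
#' @export
standardize_traits <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop_param("need at least 2 non-missing values")
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) stop_param("zero variance: cannot standardise")
  (x - mean(x[ok])) / s
}
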