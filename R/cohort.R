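#' Mean lesion diameter from biaxial CT measurement
#'
#' Serial CT measurement of a pancreatic lesion records its long and short
#' axes; the geometric mean of the two is used as the mean lesion diameter.
#'
#' @param long_axis Long axis in mm (> 0). Vectorized.
#' @param short_axis Short axis in mm (> 0). The function is symmetric in its
#'   arguments; the short <= long convention is enforced when records are
#'   built, not here.
#' @return Mean diameter in mm, between the two axes.
#' @examples
#' mean_diameter(20, 10) # sqrt(200)
#' @export
mean_diameter <- function(long_axis, short_axis) {
  if (any(!is.finite(long_axis)) || any(!is.finite(short_axis)) ||
      any(long_axis <= 0) || any(short_axis <= 0)) {
    stop("invalid measurement: axes must be positive and finite", call. = FALSE)
  }
  sqrt(long_axis * short_axis)
}

#' Lesion volume from mean diameter, sphere approximation
#'
#' @param diameter Mean lesion diameter in mm (>= 0). Vectorized.
#' @return Volume in mm^3 (pi * d^3 / 6).
#' @examples
#' sphere_volume(70) / 1000 # ~180 cm^3, the carrying-capacity sphere
#' @export
sphere_volume <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter < 0)) {
    stop("invalid measurement: diameter must be non-negative", call. = FALSE)
  }
  pi * diameter^3 / 6
}

#' Inverse of [sphere_volume()]: diameter of a sphere of given volume
#' @param volume Volume in mm^3 (>= 0).
#' @return Diameter in mm.
#' @export
sphere_diameter <- function(volume) {
  if (any(!is.finite(volume)) || any(volume < 0)) {
    stop("invalid measurement: volume must be non-negative", call. = FALSE)
  }
  (6 * volume / pi)^(1 / 3)
}

# days per month used when converting ISO scan dates to months
DAYS_PER_MONTH <- 30.4375

#' Construct a patient record
#'
#' A patient record holds the serial lesion observations (the last one being
#' the diagnostic scan), the imaging subtype label, and optional serial
#' body-composition and blood-glucose series.
#'
#' @param patient_id Opaque identifier string.
#' @param delta_class `"high"` or `"low"` imaging subtype.
#' @param observations data.frame with columns `time` (months since first
#'   observation, first row exactly 0, strictly increasing), `long_axis` and
#'   `short_axis` (mm). A `volume` column (mm^3) is computed if absent.
#' @param tissue_series Optional named list (`SAF`, `VAF`, `muscle`) of
#'   data.frames with columns `time` (months relative to diagnosis, <= 0,
#'   strictly increasing) and `value` (volume, cm^3).
#' @param bg_series Optional data.frame with columns `time` (months relative
#'   to diagnosis) and `value` (blood glucose, mg/dL).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, delta_class, observations,
                           tissue_series = NULL, bg_series = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  delta_class <- match.arg(tolower(as.character(delta_class)), c("high", "low"))
  observations <- as.data.frame(observations)
  req <- c("time", "long_axis", "short_axis")
  if (!all(req %in% names(observations))) {
    stop(sprintf("patient %s: observations need columns %s", patient_id,
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  if (nrow(observations) < 2L) {
    stop(sprintf("patient %s: at least 2 observations required", patient_id),
         call. = FALSE)
  }
  if (observations$time[1] != 0) {
    stop(sprintf("patient %s: first observation time must be 0", patient_id),
         call. = FALSE)
  }
  if (any(diff(observations$time) <= 0)) {
    stop(sprintf("patient %s: observation times must be strictly increasing",
                 patient_id), call. = FALSE)
  }
  if (any(observations$short_axis > observations$long_axis)) {
    stop(sprintf("patient %s: short axis exceeds long axis", patient_id),
         call. = FALSE)
  }
  if (is.null(observations$volume)) {
    observations$volume <- sphere_volume(
      mean_diameter(observations$long_axis, observations$short_axis))
  }
  if (!is.null(tissue_series)) {
    bad <- setdiff(names(tissue_series), c("SAF", "VAF", "muscle"))
    if (length(bad)) {
      stop(sprintf("patient %s: unknown tissue(s) %s", patient_id,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    tissue_series <- lapply(tissue_series, validate_series, patient_id)
  }
  if (!is.null(bg_series)) bg_series <- validate_series(bg_series, patient_id)
  structure(
    list(patient_id = patient_id, delta_class = delta_class,
         observations = observations, tissue_series = tissue_series,
         bg_series = bg_series),
    class = "patient_record")
}

validate_series <- function(series, patient_id) {
  series <- as.data.frame(series)
  if (!all(c("time", "value") %in% names(series))) {
    stop(sprintf("patient %s: series needs columns time, value", patient_id),
         call. = FALSE)
  }
  if (any(diff(series$time) <= 0)) {
    stop(sprintf("patient %s: series times must be strictly increasing",
                 patient_id), call. = FALSE)
  }
  if (any(series$time > 0)) {
    stop(sprintf("patient %s: series times must be <= 0 (months before diagnosis)",
                 patient_id), call. = FALSE)
  }
  series
}

#' Construct a cohort of patient records
#'
#' @param patients List of [patient_record()] objects with unique ids.
#' @param metadata Free-form provenance list (source, seed, generator config).
#' @return An object of class `pdac_cohort`.
#' @export
pdac_cohort <- function(patients, metadata = list()) {
  stopifnot(is.list(patients), length(patients) > 0L)
  if (!all(vapply(patients, inherits, logical(1), "patient_record"))) {
    stop("all elements must be patient_record objects", call. = FALSE)
  }
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate patient_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(patients) <- ids
  structure(list(patients = patients, metadata = metadata),
            class = "pdac_cohort")
}

#' @export
print.pdac_cohort <- function(x, ...) {
  cls <- delta_classes(x)
  cat(sprintf("PDAC cohort: %d patients (%d high delta, %d low delta)\n",
              length(x$patients), sum(cls == "high"), sum(cls == "low")))
  n_obs <- vapply(x$patients, function(p) nrow(p$observations), integer(1))
  cat(sprintf("Lesion observations per patient: %d-%d (median %g)\n",
              min(n_obs), max(n_obs), stats::median(n_obs)))
  has_tissue <- sum(vapply(x$patients,
                           function(p) !is.null(p$tissue_series), logical(1)))
  has_bg <- sum(vapply(x$patients,
                       function(p) !is.null(p$bg_series), logical(1)))
  cat(sprintf("Tissue series: %d patients; BG series: %d patients\n",
              has_tissue, has_bg))
  if (!is.null(x$metadata$source)) {
    cat("Source:", x$metadata$source, "\n")
  }
  invisible(x)
}

#' Delta-class labels of a cohort
#' @param cohort A `pdac_cohort`.
#' @return Named character vector of `"high"`/`"low"` per patient.
#' @export
delta_classes <- function(cohort) {
  vapply(cohort$patients, `[[`, character(1), "delta_class")
}

#' Read a cohort from CSV files
#'
#' Lesion file columns: `patient_id`, `delta_class`, `scan_time_months` (or
#' `scan_date`, ISO-8601, converted at 30.4375 days/month), `long_axis_mm`,
#' `short_axis_mm`. Times are re-expressed relative to each patient's first
#' scan. Duplicate rows sharing a timestamp have their axes averaged, with a
#' warning. Optional tissue file columns: `patient_id`, `tissue`
#' (SAF|VAF|muscle), `time_months_rel_dx`, and either `volume_cm3` or
#' `area_cm2` + `slice_thickness_mm` (volume computed as area x thickness).
#' Optional blood-glucose file columns: `patient_id`, `time_months_rel_dx`,
#' `glucose_mg_dl`.
#'
#' @param lesions_csv Path to the lesion measurements CSV.
#' @param tissue_csv,bg_csv Optional paths to the body-composition and
#'   blood-glucose CSVs.
#' @return A [pdac_cohort()].
#' @export
read_cohort <- function(lesions_csv, tissue_csv = NULL, bg_csv = NULL) {
  les <- utils::read.csv(lesions_csv, stringsAsFactors = FALSE)
  need <- c("patient_id", "delta_class", "long_axis_mm", "short_axis_mm")
  miss <- setdiff(need, names(les))
  if (length(miss)) {
    stop(sprintf("lesion file missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if ("scan_time_months" %in% names(les)) {
    les$.time <- as.numeric(les$scan_time_months)
  } else if ("scan_date" %in% names(les)) {
    les$.time <- as.numeric(as.Date(les$scan_date)) / DAYS_PER_MONTH
  } else {
    stop("lesion file needs scan_time_months or scan_date", call. = FALSE)
  }

  tissue <- if (!is.null(tissue_csv)) {
    utils::read.csv(tissue_csv, stringsAsFactors = FALSE)
  }
  if (!is.null(tissue)) {
    if (!all(c("patient_id", "tissue", "time_months_rel_dx") %in% names(tissue))) {
      stop("tissue file missing required columns", call. = FALSE)
    }
    if (!"volume_cm3" %in% names(tissue)) {
      if (!all(c("area_cm2", "slice_thickness_mm") %in% names(tissue))) {
        stop("tissue file needs volume_cm3 or area_cm2 + slice_thickness_mm",
             call. = FALSE)
      }
      tissue$volume_cm3 <- tissue_volume(tissue$area_cm2,
                                         tissue$slice_thickness_mm)
    }
  }
  bg <- if (!is.null(bg_csv)) utils::read.csv(bg_csv, stringsAsFactors = FALSE)
  if (!is.null(bg) &&
      !all(c("patient_id", "time_months_rel_dx", "glucose_mg_dl") %in% names(bg))) {
    stop("blood-glucose file missing required columns", call. = FALSE)
  }

  patients <- lapply(split(les, les$patient_id), function(d) {
    pid <- d$patient_id[1]
    d <- d[order(d$.time), , drop = FALSE]
    if (anyDuplicated(d$.time)) {
      warning(sprintf("patient %s: duplicate scan times, averaging axes", pid),
              call. = FALSE)
      d <- do.call(rbind, lapply(split(d, d$.time), function(g) {
        g$long_axis_mm[1] <- mean(g$long_axis_mm)
        g$short_axis_mm[1] <- mean(g$short_axis_mm)
        g[1, , drop = FALSE]
      }))
      d <- d[order(d$.time), , drop = FALSE]
    }
    if (nrow(d) < 2L) {
      stop(sprintf("patient %s: fewer than 2 observations", pid), call. = FALSE)
    }
    if (length(unique(d$delta_class)) != 1L) {
      stop(sprintf("patient %s: inconsistent delta_class", pid), call. = FALSE)
    }
    obs <- data.frame(time = d$.time - d$.time[1],
                      long_axis = d$long_axis_mm,
                      short_axis = d$short_axis_mm)
    ts <- NULL
    if (!is.null(tissue)) {
      tp <- tissue[tissue$patient_id == pid, , drop = FALSE]
      if (nrow(tp)) {
        ts <- lapply(split(tp, tp$tissue), function(g) {
          g <- g[order(g$time_months_rel_dx), , drop = FALSE]
          data.frame(time = g$time_months_rel_dx, value = g$volume_cm3)
        })
      }
    }
    bs <- NULL
    if (!is.null(bg)) {
      bp <- bg[bg$patient_id == pid, , drop = FALSE]
      if (nrow(bp)) {
        bp <- bp[order(bp$time_months_rel_dx), , drop = FALSE]
        bs <- data.frame(time = bp$time_months_rel_dx,
                         value = bp$glucose_mg_dl)
      }
    }
    patient_record(pid, d$delta_class[1], obs, tissue_series = ts,
                   bg_series = bs)
  })
  pdac_cohort(unname(patients),
              metadata = list(source = normalizePath(lesions_csv)))
}

# full-precision numeric formatting so CSV round-trips are exact
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a cohort to CSV files
#'
#' Writes the lesion schema of [read_cohort()] to `file.path(dir, "lesions.csv")`
#' and, when present, tissue and blood-glucose series to `tissue.csv` and
#' `bg.csv`. Numeric fields are written at full precision so that
#' `read_cohort()` reproduces them exactly.
#'
#' @param cohort A [pdac_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pdac_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  les <- do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$patient_id, delta_class = p$delta_class,
               scan_time_months = fmt_num(p$observations$time),
               long_axis_mm = fmt_num(p$observations$long_axis),
               short_axis_mm = fmt_num(p$observations$short_axis))
  }))
  paths <- file.path(dir, "lesions.csv")
  utils::write.csv(les, paths[1], row.names = FALSE, quote = FALSE)

  tis <- do.call(rbind, lapply(cohort$patients, function(p) {
    if (is.null(p$tissue_series)) return(NULL)
    do.call(rbind, lapply(names(p$tissue_series), function(tn) {
      s <- p$tissue_series[[tn]]
      data.frame(patient_id = p$patient_id, tissue = tn,
                 time_months_rel_dx = fmt_num(s$time),
                 volume_cm3 = fmt_num(s$value))
    }))
  }))
  if (!is.null(tis)) {
    tp <- file.path(dir, "tissue.csv")
    utils::write.csv(tis, tp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, tp)
  }
  bg <- do.call(rbind, lapply(cohort$patients, function(p) {
    if (is.null(p$bg_series)) return(NULL)
    data.frame(patient_id = p$patient_id,
               time_months_rel_dx = fmt_num(p$bg_series$time),
               glucose_mg_dl = fmt_num(p$bg_series$value))
  }))
  if (!is.null(bg)) {
    bp <- file.path(dir, "bg.csv")
    utils::write.csv(bg, bp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, bp)
  }
  invisible(paths)
}
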