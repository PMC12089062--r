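need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (cl in cols) {
    if (!is.numeric(df[[cl]]) && !is.logical(df[[cl]])) {
      abort(paste0(what, " column `", cl, "` must be numeric."))
    }
  }
  invisible(df)
}

#' Write synthetic survey tables to CSV
#'
#' Writes the living-squirrel survey tables, DOR records, risk dataset and
#' citizen-science table to the CSV schemas that [read_survey_tables()]
#' consumes, plus a JSON sidecar (`truth.json`) recording the generating
#' parameters and seed when the data are synthetic.
#'
#' @param dir Output directory (created if needed).
#' @param survey A `squirrel_survey_data` list, or `NULL` to skip.
#' @param dor DOR records tibble, or `NULL`.
#' @param risk Risk dataset tibble, or `NULL`.
#' @param citizen A `contingency_2x2`, or `NULL`.
#' @param truth A [truth_params()] for the sidecar, or `NULL`.
#' @param seed Seed to record in the sidecar.
#' @return Named character vector of the files written, invisibly.
#' @export
write_survey_tables <- function(dir, survey = NULL, dor = NULL, risk = NULL,
                                citizen = NULL, truth = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(as.data.frame(df), p, row.names = FALSE)
    paths[[sub("[.]csv$", "", name)]] <<- p
  }
  if (!is.null(survey)) {
    wr(survey$sites[, c("site", "distance_km", "camera")], "sites.csv")
    wr(survey$counts[, c("site", "survey", "temp", "count_melanic",
                         "count_gray")], "counts.csv")
    wr(survey$cameras[, c("site", "day", "temp", "det_melanic",
                          "det_gray")], "cameras.csv")
  }
  if (!is.null(dor)) wr(dor[, c("distance_km", "morph")], "dor.csv")
  if (!is.null(risk)) wr(risk, "risk.csv")
  if (!is.null(citizen)) {
    df <- as.data.frame(unclass(as.matrix(citizen)))
    df <- cbind(status = rownames(df), df)
    p <- file.path(dir, "citizen.csv")
    write.csv(df, p, row.names = FALSE)
    paths[["citizen"]] <- p
  }
  if (!is.null(truth) || !is.null(seed)) {
    side <- list(seed = seed)
    if (!is.null(truth)) side$truth <- unclass(truth)
    p <- file.path(dir, "truth.json")
    jsonlite::write_json(side, p, auto_unbox = TRUE, digits = NA)
    paths[["truth"]] <- p
  }
  invisible(paths)
}

#' Read survey tables from CSV
#'
#' Reads any subset of the schemas written by [write_survey_tables()] and
#' rebuilds the typed datasets, re-deriving standardizers from the data
#' (distance over sites, temperature pooled over point-count and camera
#' occasions). Column names and invariants are validated with informative
#' errors.
#'
#' @param dir Directory containing the CSVs, or `NULL` when giving paths.
#' @param sites,counts,cameras,dor,risk,citizen Optional explicit paths
#'   overriding `dir` defaults. Missing files are skipped.
#' @return A list with any of `survey` (`squirrel_survey_data`), `dor`,
#'   `risk`, `citizen` that could be read.
#' @export
read_survey_tables <- function(dir = NULL, sites = NULL, counts = NULL,
                               cameras = NULL, dor = NULL, risk = NULL,
                               citizen = NULL) {
  pick <- function(explicit, name) {
    if (!is.null(explicit)) return(explicit)
    if (is.null(dir)) return(NULL)
    p <- file.path(dir, name)
    if (file.exists(p)) p else NULL
  }
  out <- list()
  p_sites <- pick(sites, "sites.csv")
  p_counts <- pick(counts, "counts.csv")
  p_cams <- pick(cameras, "cameras.csv")
  if (!is.null(p_sites) && !is.null(p_counts)) {
    st <- tibble::as_tibble(read.csv(p_sites))
    need_cols(st, c("site", "distance_km", "camera"), "sites.csv")
    if (any(st$distance_km <= 0)) abort("sites.csv: distances must be > 0.")
    cn <- tibble::as_tibble(read.csv(p_counts))
    need_cols(cn, c("site", "survey", "temp", "count_melanic", "count_gray"),
              "counts.csv")
    if (any(cn$count_melanic < 0) || any(cn$count_gray < 0)) {
      abort("counts.csv: counts must be nonnegative.")
    }
    if (!all(cn$site %in% st$site)) abort("counts.csv: unknown site ids.")
    cam <- if (!is.null(p_cams)) tibble::as_tibble(read.csv(p_cams)) else
      tibble::tibble(site = integer(0), day = integer(0), temp = numeric(0),
                     det_melanic = integer(0), det_gray = integer(0))
    need_cols(cam, c("site", "day", "temp", "det_melanic", "det_gray"),
              "cameras.csv")
    if (nrow(cam) && !all(c(cam$det_melanic, cam$det_gray) %in% c(0, 1))) {
      abort("cameras.csv: detections must be binary.")
    }
    if (nrow(cam) && !all(cam$site %in% st$site[as.logical(st$camera)])) {
      abort("cameras.csv: camera records at sites not flagged as camera sites.")
    }
    dstd <- standardize(st$distance_km)
    tstd <- standardize(c(cn$temp, cam$temp))
    st$dist_std <- dstd$values
    cn$temp_std <- tstd$values[seq_len(nrow(cn))]
    cam$temp_std <- tstd$values[nrow(cn) + seq_len(nrow(cam))]
    out$survey <- structure(
      list(sites = st[, c("site", "distance_km", "dist_std", "camera")],
           counts = cn[, c("site", "survey", "temp", "temp_std",
                           "count_melanic", "count_gray")],
           cameras = cam[, c("site", "day", "temp", "temp_std",
                             "det_melanic", "det_gray")],
           latent = NULL,
           standardizers = list(
             distance = list(mean = dstd$mean, sd = dstd$sd),
             temperature = list(mean = tstd$mean, sd = tstd$sd))),
      class = "squirrel_survey_data")
  }
  p_dor <- pick(dor, "dor.csv")
  if (!is.null(p_dor)) {
    dd <- tibble::as_tibble(read.csv(p_dor))
    need_cols(dd, c("distance_km", "morph"), "dor.csv")
    if (!all(dd$morph %in% c(0, 1))) abort("dor.csv: morph must be 0/1.")
    if (nrow(dd) >= 2) {
      std <- standardize(dd$distance_km)
      dd$dist_std <- std$values
      attr(dd, "standardizer") <- list(mean = std$mean, sd = std$sd)
    }
    out$dor <- dd
  }
  p_risk <- pick(risk, "risk.csv")
  if (!is.null(p_risk)) {
    rk <- tibble::as_tibble(read.csv(p_risk))
    need_cols(rk, "outcome", "risk.csv")
    if (!all(rk$outcome %in% c(0, 1))) abort("risk.csv: outcome must be 0/1.")
    out$risk <- rk
  }
  p_cit <- pick(citizen, "citizen.csv")
  if (!is.null(p_cit)) {
    ct <- read.csv(p_cit)
    need <- c("status", "melanic", "gray")
    miss <- setdiff(need, names(ct))
    if (length(miss)) {
      abort(paste0("citizen.csv is missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    rownames(ct) <- ct$status
    m <- as.matrix(ct[c("dead", "alive"), c("melanic", "gray")])
    out$citizen <- make_citizen_table(
      total_melanic = sum(m[, "melanic"]), dead_melanic = m["dead", "melanic"],
      total_gray = sum(m[, "gray"]), dead_gray = m["dead", "gray"])
  }
  out
}

#' Serialize a cline or difference curve
#'
#' @param curve A curve tibble (`distance_km`, `mean`, `lower95`,
#'   `upper95`).
#' @param path Output path; `.csv` or `.json` chosen by extension.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  need_cols(curve, c("distance_km", "mean", "lower95", "upper95"), "curve")
  if (grepl("[.]json$", path)) {
    jsonlite::write_json(as.data.frame(curve), path, digits = NA)
  } else {
    write.csv(as.data.frame(curve), path, row.names = FALSE)
  }
  invisible(path)
}
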