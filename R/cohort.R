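#' Construct a longitudinal cohort
#'
#' A cohort bundles one row of baseline covariates per patient with a long
#' table of timestamped outcome observations (days since surgery, outcome in
#' seconds). This is the container every downstream stage (anchor imputation,
#' matching, trajectory fitting, tuning) operates on.
#'
#' @param covariates data frame with columns `patient_id`, `age` (years),
#'   `sex` (`"male"`/`"female"`), `bmi` (kg/m^2), `preop` (preoperative
#'   outcome, seconds). One row per patient; ids must be unique.
#' @param observations data frame with columns `patient_id`, `time` (days
#'   since surgery, >= 0) and `value` (outcome in seconds, > 0). May be empty
#'   for some patients.
#' @param label free-text label, e.g. `"train"` or `"test"`.
#' @return An object of class `cohort`: a list with elements `covariates`,
#'   `observations` (sorted by patient then time) and `label`.
#' @export
cohort <- function(covariates, observations, label = "") {
  covariates <- as.data.frame(covariates)
  observations <- as.data.frame(observations)
  need_cov <- c("patient_id", "age", "sex", "bmi", "preop")
  need_obs <- c("patient_id", "time", "value")
  miss <- setdiff(need_cov, names(covariates))
  if (length(miss) > 0L) {
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(need_obs, names(observations))
  if (length(miss) > 0L) {
    stop("observation table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  covariates$patient_id <- as.character(covariates$patient_id)
  observations$patient_id <- as.character(observations$patient_id)
  if (nrow(covariates) < 1L) stop("a cohort needs at least one patient", call. = FALSE)
  if (anyDuplicated(covariates$patient_id)) {
    stop("duplicate patient_id in covariate table", call. = FALSE)
  }
  if (nrow(observations) > 0L) {
    if (!is.numeric(observations$time) || !is.numeric(observations$value)) {
      stop("observation time and value must be numeric", call. = FALSE)
    }
    bad <- !is.finite(observations$time) | observations$time < 0
    if (any(bad)) stop("observation times must be finite and >= 0", call. = FALSE)
    bad <- !is.finite(observations$value) | observations$value <= 0
    if (any(bad)) stop("observation values must be finite and > 0", call. = FALSE)
    dup <- duplicated(observations[, c("patient_id", "time")])
    if (any(dup)) {
      stop("duplicate (patient_id, time) observation rows: ",
           paste(utils::head(observations$patient_id[dup], 3L), collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(observations$patient_id, covariates$patient_id)
    if (length(unknown) > 0L) {
      stop("observations reference patient(s) absent from the covariate table: ",
           paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
    }
    observations <- observations[order(observations$patient_id, observations$time),
                                 need_obs, drop = FALSE]
  } else {
    observations <- data.frame(patient_id = character(), time = numeric(),
                               value = numeric())
  }
  rownames(covariates) <- NULL
  rownames(observations) <- NULL
  structure(list(covariates = covariates[, need_cov, drop = FALSE],
                 observations = observations,
                 label = as.character(label)[1L]),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort%s: %d patients, %d observations>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$covariates), nrow(x$observations)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a [cohort()] object
#' @return integer patient count
#' @export
n_patients <- function(cohort) nrow(cohort$covariates)

#' Observations of selected patients
#'
#' @param cohort a [cohort()] object
#' @param ids character vector of patient ids
#' @return data frame of the pooled observations of `ids`
#' @export
patient_observations <- function(cohort, ids) {
  cohort$observations[cohort$observations$patient_id %in% ids, , drop = FALSE]
}

#' Default column-name layout of the long-format interchange CSV
#'
#' @param patient_id,age,sex,bmi,preop,time,value column names in the file
#' @return named list mapping internal field names to file column names
#' @export
cohort_layout <- function(patient_id = "patient_id", age = "age", sex = "sex",
                          bmi = "bmi", preop = "preop_tug",
                          time = "time_days", value = "tug_seconds") {
  list(patient_id = patient_id, age = age, sex = sex, bmi = bmi,
       preop = preop, time = time, value = value)
}

#' Read a cohort from a long-format CSV file
#'
#' One row per assessment; baseline covariates repeated on every row of a
#' patient. A patient may appear with empty `time`/`value` fields on a single
#' row, which encodes "covariates known, no postoperative observations yet".
#'
#' @param path CSV file path (comma-separated, header row, decimal point)
#' @param layout column-name mapping from [cohort_layout()]
#' @param label cohort label
#' @return a validated [cohort()]
#' @export
read_cohort <- function(path, layout = cohort_layout(), label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unlist(layout), names(raw))
  if (length(miss) > 0L) {
    stop("input file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (fld in c("age", "bmi", "preop", "time", "value")) {
    col <- raw[[layout[[fld]]]]
    if (is.character(col)) {
      conv <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & nzchar(trimws(col)) & is.na(conv))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                     layout[[fld]], bad[1L], col[bad[1L]]), call. = FALSE)
      }
      raw[[layout[[fld]]]] <- conv
    }
  }
  id <- as.character(raw[[layout$patient_id]])
  cov <- data.frame(patient_id = id,
                    age = raw[[layout$age]],
                    sex = tolower(as.character(raw[[layout$sex]])),
                    bmi = raw[[layout$bmi]],
                    preop = raw[[layout$preop]],
                    stringsAsFactors = FALSE)
  cov <- cov[!duplicated(cov$patient_id), , drop = FALSE]
  keep <- !is.na(raw[[layout$time]]) & !is.na(raw[[layout$value]])
  obs <- data.frame(patient_id = id[keep],
                    time = raw[[layout$time]][keep],
                    value = raw[[layout$value]][keep],
                    stringsAsFactors = FALSE)
  cohort(cov, obs, label = label)
}

#' Write a cohort to a long-format CSV file
#'
#' Inverse of [read_cohort()]: one row per observation with the patient's
#' covariates repeated; a patient without observations is written as a single
#' covariate-only row with empty time/value fields so that the round trip
#' preserves the full patient list.
#'
#' @param cohort a [cohort()]
#' @param path output file path
#' @param layout column-name mapping from [cohort_layout()]
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path, layout = cohort_layout()) {
  stopifnot(inherits(cohort, "cohort"))
  obs <- cohort$observations
  cov <- cohort$covariates
  no_obs <- setdiff(cov$patient_id, obs$patient_id)
  if (length(no_obs) > 0L) {
    obs <- rbind(obs, data.frame(patient_id = no_obs, time = NA_real_,
                                 value = NA_real_))
  }
  out <- merge(obs, cov, by = "patient_id", sort = FALSE)
  out <- out[order(out$patient_id, out$time), , drop = FALSE]
  out <- data.frame(out$patient_id, out$age, out$sex, out$bmi, out$preop,
                    out$time, out$value)
  names(out) <- unlist(layout[c("patient_id", "age", "sex", "bmi", "preop",
                                "time", "value")])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Screen a cohort against the analysis inclusion rules
#'
#' Only patients with a recorded preoperative outcome, complete baseline
#' covariates, and at least `min_obs` postoperative observations inside the
#' follow-up window are analyzable. Observations beyond `horizon` days are
#' dropped with a warning (late follow-up is outside the modeled range);
#' patients failing the rules are removed and listed in the report.
#'
#' @param cohort a [cohort()]
#' @param min_obs minimum number of in-window postoperative observations
#' @param horizon follow-up window in days (default 180, the first six
#'   postoperative months)
#' @return list with `cohort` (the filtered cohort) and `report` (data frame
#'   `patient_id`, `issue`; zero rows when every patient is compliant)
#' @export
validate_cohort <- function(cohort, min_obs = 1L, horizon = 180) {
  stopifnot(inherits(cohort, "cohort"))
  cov <- cohort$covariates
  obs <- cohort$observations
  report <- data.frame(patient_id = character(), issue = character(),
                       stringsAsFactors = FALSE)
  note <- function(ids, issue) {
    if (length(ids) > 0L) {
      report <<- rbind(report, data.frame(patient_id = ids, issue = issue,
                                          stringsAsFactors = FALSE))
    }
  }
  late <- obs$time > horizon
  if (any(late)) {
    note(unique(obs$patient_id[late]), "observations beyond horizon dropped")
    warning(sum(late), " observation(s) beyond ", horizon,
            " days dropped", call. = FALSE)
    obs <- obs[!late, , drop = FALSE]
  }
  cov_num <- cov[, c("age", "bmi", "preop")]
  incomplete <- !stats::complete.cases(cov_num) |
    !(cov$sex %in% c("male", "female")) |
    (!is.na(cov$bmi) & cov$bmi <= 0) | (!is.na(cov$preop) & cov$preop <= 0)
  note(cov$patient_id[incomplete & is.na(cov$preop)], "preop outcome missing")
  note(cov$patient_id[incomplete & !is.na(cov$preop)],
       "incomplete baseline covariates")
  n_obs <- table(factor(obs$patient_id, levels = cov$patient_id))
  few <- as.vector(n_obs) < min_obs
  note(cov$patient_id[few & !incomplete],
       sprintf("fewer than %d postoperative observation(s)", min_obs))
  keep <- cov$patient_id[!incomplete & !few]
  if (length(keep) < 1L) stop("no analyzable patients remain", call. = FALSE)
  out <- cohort(cov[cov$patient_id %in% keep, , drop = FALSE],
                obs[obs$patient_id %in% keep, , drop = FALSE],
                label = cohort$label)
  list(cohort = out, report = report)
}
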