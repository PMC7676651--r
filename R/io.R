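#' Read and write progenitor count tables
#'
#' The count CSV has columns `patient_id,population,timepoint,count`, one
#' row per patient x population x time point, counts in cells per 10^6
#' lympho-monocytic events. `read_count_table()` validates the closed
#' time-point and population vocabularies, key uniqueness and count
#' non-negativity, and returns rows in normalised order (patient, then
#' canonical population order, then temporal order); `write_count_table()`
#' writes the same normalised, byte-stable layout, so write-then-read is
#' the identity on validated tables.
#'
#' @param path CSV file path.
#' @param allow_missing If `TRUE`, empty `count` cells are kept as `NA`;
#'   by default they are rejected because downstream operations need
#'   complete six-point series.
#' @return `read_count_table()`: a validated `data.frame`;
#'   `write_count_table()`: the path, invisibly.
#' @export
read_count_table <- function(path, allow_missing = FALSE) {
  if (!file.exists(path)) vk_stop("count table file not found: %s", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  validate_count_table(x, allow_missing = allow_missing)
}

#' @rdname read_count_table
#' @param x A count table `data.frame`.
#' @export
write_count_table <- function(x, path) {
  x <- validate_count_table(x, allow_missing = TRUE)
  x$count <- format_num(x$count)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_count_table <- function(x, allow_missing = FALSE) {
  need <- c("patient_id", "population", "timepoint", "count")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    vk_stop("count table is missing column(s): %s",
            paste(miss, collapse = ", "), class = "vk_validation_error")
  }
  x <- x[, need, drop = FALSE]
  x$patient_id <- as.character(x$patient_id)
  bad_tp <- setdiff(unique(x$timepoint), vk_timepoints())
  if (length(bad_tp) > 0) {
    vk_stop("unknown time point(s) in count table: %s (allowed: %s)",
            paste(bad_tp, collapse = ", "),
            paste(vk_timepoints(), collapse = ", "),
            class = "vk_validation_error")
  }
  bad_pop <- setdiff(unique(x$population), vk_populations())
  if (length(bad_pop) > 0) {
    vk_stop("unknown population(s) in count table: %s",
            paste(bad_pop, collapse = ", "), class = "vk_validation_error")
  }
  if (!is.numeric(x$count)) {
    vk_stop("count column must be numeric", class = "vk_validation_error")
  }
  if (anyNA(x$count) && !allow_missing) {
    vk_stop("count table has %d missing count(s) (first at row %d); pass allow_missing = TRUE to keep them",
            sum(is.na(x$count)), which(is.na(x$count))[1L],
            class = "vk_validation_error")
  }
  neg <- which(!is.na(x$count) & x$count < 0)
  if (length(neg) > 0) {
    vk_stop("negative count at row %d (patient %s, %s, %s)",
            neg[1L], x$patient_id[neg[1L]], x$population[neg[1L]],
            x$timepoint[neg[1L]], class = "vk_validation_error")
  }
  key <- paste(x$patient_id, x$population, x$timepoint, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    vk_stop("duplicate (patient_id, population, timepoint) key at row %d: (%s, %s, %s)",
            dup[1L], x$patient_id[dup[1L]], x$population[dup[1L]],
            x$timepoint[dup[1L]], class = "vk_validation_error")
  }
  x <- x[order(x$patient_id,
               match(x$population, vk_populations()),
               match(x$timepoint, vk_timepoints())), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read and write patient tables
#'
#' The patient CSV has mandatory columns `patient_id` and `ne_dose`
#' (total norepinephrine, mg/kg), optional `group` (`G1`/`G2`; must be
#' consistent with `ne_dose` under the 0.02 mg/kg rule when present,
#' empty cells mean unassigned) and `euroscore2` (EuroSCORE II estimated
#' % mortality), plus any further covariate columns, which are preserved.
#'
#' @param path CSV file path.
#' @return `read_patient_table()`: a validated `data.frame` with one row
#'   per patient; `write_patient_table()`: the path, invisibly.
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) vk_stop("patient table file not found: %s", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  validate_patient_table(x)
}

#' @rdname read_patient_table
#' @param x A patient table `data.frame`.
#' @export
write_patient_table <- function(x, path) {
  x <- validate_patient_table(x)
  num <- vapply(x, is.numeric, logical(1)) & names(x) != "renal_failure"
  x[num] <- lapply(x[num], format_num)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_patient_table <- function(x) {
  need <- c("patient_id", "ne_dose")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    vk_stop("patient table is missing column(s): %s",
            paste(miss, collapse = ", "), class = "vk_validation_error")
  }
  x$patient_id <- as.character(x$patient_id)
  dup <- which(duplicated(x$patient_id))
  if (length(dup) > 0) {
    vk_stop("duplicate patient_id '%s' at row %d", x$patient_id[dup[1L]],
            dup[1L], class = "vk_validation_error")
  }
  if (!is.numeric(x$ne_dose)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x$ne_dose))))[1L]
    vk_stop("non-numeric ne_dose '%s' at row %d", x$ne_dose[bad], bad,
            class = "vk_validation_error")
  }
  if (any(x$ne_dose < 0, na.rm = TRUE)) {
    vk_stop("negative ne_dose at row %d", which(x$ne_dose < 0)[1L],
            class = "vk_validation_error")
  }
  if (!"group" %in% names(x)) {
    x$group <- NA_character_
  }
  x$group[!is.na(x$group) & x$group == ""] <- NA_character_
  bad_grp <- which(!is.na(x$group) & !x$group %in% c("G1", "G2"))
  if (length(bad_grp) > 0) {
    vk_stop("unknown group '%s' at row %d (allowed: G1, G2 or empty)",
            x$group[bad_grp[1L]], bad_grp[1L], class = "vk_validation_error")
  }
  assigned <- !is.na(x$group)
  incons <- which(assigned & x$group != assign_group(x$ne_dose[assigned]))
  if (length(incons) > 0) {
    i <- incons[1L]
    vk_stop("group '%s' of patient %s conflicts with ne_dose %g under the 0.02 mg/kg rule",
            x$group[i], x$patient_id[i], x$ne_dose[i],
            class = "vk_validation_error")
  }
  if ("euroscore2" %in% names(x)) {
    if (!is.numeric(x$euroscore2)) {
      vk_stop("non-numeric euroscore2 column", class = "vk_validation_error")
    }
    if (any(x$euroscore2 < 0, na.rm = TRUE)) {
      vk_stop("negative euroscore2 at row %d",
              which(x$euroscore2 < 0)[1L], class = "vk_validation_error")
    }
  }
  lead <- intersect(c("patient_id", "ne_dose", "group", "euroscore2"), names(x))
  x <- x[, c(lead, setdiff(names(x), lead)), drop = FALSE]
  rownames(x) <- NULL
  x
}

# fixed decimal formatting so that write -> read -> write is byte-stable
format_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) NA_character_ else format(z, digits = 15, scientific = FALSE)
  }, character(1))
  out
}
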