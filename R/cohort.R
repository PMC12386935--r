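#' Cohort table of daily individual rearing records
#'
#' A cohort holds one row per individual per day alive: the individual's id,
#' its age in days (0 = day of oviposition), the stage it occupied that day,
#' the number of eggs it laid that day (adult females only), and its sex
#' (`"female"`, `"male"`, or `"unknown"` for individuals dying before
#' adulthood). An individual's last row is its last day alive; its death age is
#' that age + 1. No censoring is supported.
#'
#' @param data A data.frame with columns `id`, `day`, `stage`, `eggs`, `sex`.
#'   `eggs` may be `NA` (treated as 0).
#' @param schema A [stage_schema()]; defaults to [default_schema()].
#'
#' @return An object of class `cohort_table`: a list with elements `data`
#'   (canonicalised records sorted by id and day), `schema`, `n` (number of
#'   individuals, i.e. initial eggs) and `omega` (maximum death age).
#' @seealso [read_cohort()], [validate_cohort()], [generate_cohort()]
#' @export
cohort_table <- function(data, schema = default_schema()) {
  req <- c("id", "day", "stage", "eggs", "sex")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("cohort format error: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L)
    stop("cohort format error: no records")
  data <- data.frame(id = as.character(data$id),
                     day = as.integer(data$day),
                     stage = as.character(data$stage),
                     eggs = ifelse(is.na(data$eggs), 0, as.numeric(data$eggs)),
                     sex = as.character(data$sex),
                     stringsAsFactors = FALSE)
  bad <- setdiff(unique(data$stage), schema$stages)
  if (length(bad))
    stop("cohort format error: unknown stage label(s): ", paste(bad, collapse = ", "))
  data <- data[order(data$id, data$day), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, schema = schema,
                 n = length(unique(data$id)),
                 omega = max(data$day) + 1L),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> n = ", x$n, " individuals, omega = ", x$omega,
      " days, ", nrow(x$data), " daily records\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cohort_table <- function(x, ...) x$data

#' Validate a cohort against the data-model invariants
#'
#' Checks every invariant of the cohort data model and reports violations
#' rather than throwing: consecutive ages from 0, egg stage on day 0,
#' non-decreasing stage sequence with only optional (supernumerary) stages
#' skipped, a single adult stage per individual, eggs only on adult-female
#' days, and sex labels consistent with the stages reached.
#'
#' @param cohort A [cohort_table()].
#' @return A data.frame with columns `id`, `rule`, `message`; zero rows iff
#'   the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- cohort$data
  sch <- cohort$schema
  viol <- list()
  add <- function(id, rule, message)
    viol[[length(viol) + 1L]] <<- data.frame(id = id, rule = rule,
                                             message = message)

  si <- match(d$stage, sch$stages)
  new_id <- c(TRUE, d$id[-1L] != d$id[-nrow(d)])
  ord <- order(d$id, d$day)
  if (is.unsorted(ord)) { # cohort_table() sorts; guard for hand-built objects
    d <- d[ord, ]; si <- si[ord]
    new_id <- c(TRUE, d$id[-1L] != d$id[-nrow(d)])
  }

  # ages consecutive starting at 0
  start_bad <- d$id[new_id & d$day != 0L]
  if (length(start_bad))
    add(unique(start_bad), "consecutive_days", "first record is not day 0")
  step <- diff(d$day)
  gap <- which(!new_id[-1L] & step != 1L)
  if (length(gap))
    add(unique(d$id[gap + 1L]), "consecutive_days", "ages are not consecutive")

  # day 0 must be EGG
  egg_bad <- d$id[new_id & d$day == 0L & d$stage != "EGG"]
  if (length(egg_bad))
    add(unique(egg_bad), "egg_first", "day 0 stage is not EGG")

  # stage sequence non-decreasing; jumps may only skip optional stages or the
  # alternative adult stage (a male goes PUPA -> ADULT_M past ADULT_F)
  from <- si[-nrow(d)]; to <- si[-1L]
  within <- !new_id[-1L]
  regress <- which(within & to < from)
  if (length(regress))
    add(unique(d$id[regress + 1L]), "stage_order", "stage sequence regresses")
  jump <- which(within & to > from + 1L)
  for (k in jump) {
    skipped <- sch$stages[(from[k] + 1L):(to[k] - 1L)]
    allowed <- skipped %in% sch$optional |
      (skipped %in% sch$adult & !sch$stages[to[k]] %in% skipped)
    if (!all(allowed))
      add(d$id[k + 1L], "stage_order",
          paste("skips mandatory stage(s):",
                paste(skipped[!allowed], collapse = ", ")))
  }

  per <- function(x, f) tapply(x, d$id, f)
  has_f <- per(d$stage, function(s) any(s == sch$female))
  has_m <- if (length(sch$male)) per(d$stage, function(s) any(s %in% sch$male))
           else has_f & FALSE
  both <- names(has_f)[has_f & has_m]
  if (length(both))
    add(both, "single_adult_stage", "individual occupies both adult stages")

  # eggs only on adult-female days, never negative
  neg <- d$id[d$eggs < 0]
  if (length(neg))
    add(unique(neg), "eggs_nonnegative", "negative egg count")
  misplaced <- d$id[d$eggs > 0 & d$stage != sch$female]
  if (length(misplaced))
    add(unique(misplaced), "eggs_female_only",
        "eggs recorded outside the adult female stage")

  # sex consistent with stages reached
  sex <- per(d$sex, function(s) {
    u <- unique(s)
    if (length(u) == 1L) u else NA_character_
  })
  mixed <- names(sex)[is.na(sex)]
  if (length(mixed))
    add(mixed, "sex_constant", "sex label varies across days")
  expect <- ifelse(has_f, "female", ifelse(has_m, "male", "unknown"))
  wrong <- names(sex)[!is.na(sex) & sex != expect]
  if (length(wrong))
    add(wrong, "sex_consistent",
        "sex label inconsistent with adult stage reached (unknown only for pre-adult deaths)")

  if (!length(viol))
    return(data.frame(id = character(), rule = character(),
                      message = character()))
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}

#' Read a cohort from a delimited daily-record file
#'
#' The file is comma-delimited UTF-8 text with a header and columns
#' `id,day,stage,eggs,sex`, one row per individual per day alive; the `eggs`
#' column may be blank (or 0) on non-laying days. The cohort is validated on
#' read; any invariant violation is an error naming the offending individual.
#'
#' @param path Path to the CSV file.
#' @inheritParams cohort_table
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character")),
    error = function(e) stop("cohort format error: ", conditionMessage(e)))
  if (nrow(raw) == 0L)
    stop("cohort format error: file contains no records")
  cohort <- cohort_table(raw, schema)
  v <- validate_cohort(cohort)
  if (nrow(v))
    stop("cohort validation error:\n",
         paste(sprintf("  [%s] %s: %s", v$id, v$rule, v$message),
               collapse = "\n"))
  cohort
}

#' Write a cohort to a delimited daily-record file
#'
#' Writes the format read by [read_cohort()]; the round trip
#' `read_cohort(write_cohort(x))` reproduces `x` exactly. Egg counts are left
#' blank on non-laying days.
#'
#' @param cohort A valid [cohort_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- cohort$data
  out <- data.frame(id = d$id, day = d$day, stage = d$stage,
                    eggs = ifelse(d$eggs > 0, format(d$eggs, trim = TRUE,
                                                     scientific = FALSE), ""),
                    sex = d$sex, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- internal per-individual arrays ----------------------------------------
# Flattens a cohort into per-individual vectors/matrices used by the life
# table, bootstrap and summary code. Ages are 0..omega-1 (columns 1..omega).
cohort_arrays <- function(cohort) {
  d <- cohort$data
  sch <- cohort$schema
  ids <- unique(d$id)
  n <- length(ids)
  row_of <- match(d$id, ids)
  omega <- cohort$omega

  death_age <- tabulate(row_of, nbins = n)   # rows per individual = days alive

  E <- matrix(0, n, omega)
  E[cbind(row_of, d$day + 1L)] <- d$eggs

  is_adult_row <- d$stage %in% sch$adult
  emergence <- rep(NA_real_, n)
  if (any(is_adult_row)) {
    em <- tapply(d$day[is_adult_row], row_of[is_adult_row], min)
    emergence[as.integer(names(em))] <- as.numeric(em)
  }
  sex <- as.character(tapply(d$sex, row_of, function(s) s[1L])[as.character(seq_len(n))])

  total_eggs <- rowSums(E)
  egg_rows <- d$eggs > 0
  first_egg <- rep(NA_real_, n)
  if (any(egg_rows)) {
    fe <- tapply(d$day[egg_rows], row_of[egg_rows], min)
    first_egg[as.integer(names(fe))] <- as.numeric(fe)
  }
  ovi_days <- rowSums(E > 0)

  # days spent in each stage; NA when the individual died inside the stage
  # (incomplete) except for adult stages, where death defines the longevity
  Dur <- matrix(NA_real_, n, sch$beta, dimnames = list(ids, sch$stages))
  cnt <- table(factor(row_of, levels = seq_len(n)),
               factor(d$stage, levels = sch$stages))
  Dur[] <- as.numeric(cnt)
  Dur[Dur == 0] <- NA_real_
  last_stage <- tapply(d$stage, row_of, function(s) s[length(s)])
  last_stage <- as.character(last_stage[as.character(seq_len(n))])
  died_inside <- !(last_stage %in% sch$adult)
  Dur[cbind(which(died_inside), match(last_stage[died_inside], sch$stages))] <- NA_real_

  larv <- larval_stages(sch)
  n_instars <- rowSums(cnt[, larv, drop = FALSE] > 0)  # larval stages entered
  reached_pupa <- cnt[, pupal_stage(sch)] > 0

  list(ids = ids, n = n, omega = omega, schema = sch,
       death_age = as.numeric(death_age), sex = sex,
       E = E, total_eggs = total_eggs, first_egg = first_egg,
       ovi_days = ovi_days, emergence = emergence, Dur = Dur,
       n_instars = as.numeric(n_instars), reached_pupa = as.logical(reached_pupa))
}

# Resample individuals with replacement (the bootstrap unit is the whole life
# history); ids are suffixed to stay unique.
resample_cohort <- function(cohort, idx = NULL) {
  ids <- unique(cohort$data$id)
  if (is.null(idx)) idx <- sample.int(length(ids), replace = TRUE)
  pieces <- split(cohort$data, factor(cohort$data$id, levels = ids))
  out <- pieces[idx]
  for (k in seq_along(out)) out[[k]]$id <- sprintf("b%04d_%s", k, out[[k]]$id)
  cohort_table(do.call(rbind, out), cohort$schema)
}
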