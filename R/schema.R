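#' Stage schema for an age-stage life table
#'
#' Defines the ordered developmental stages of a cohort: the egg stage first,
#' larval instars (some of which may be supernumerary and skipped by most
#' individuals), a pupal stage, and the two adult stages last. The number of
#' stages is the stage dimension (beta) of every age-stage matrix.
#'
#' @param stages Character vector of stage labels in developmental order.
#' @param optional Subset of `stages` that individuals may skip (supernumerary
#'   instars). Must be contiguous and precede the pupal stage.
#' @param adult Labels of the adult stages (default: the last two stages).
#' @param female Label of the adult female stage (the only stage that can lay
#'   eggs).
#'
#' @return An object of class `stage_schema`.
#' @examples
#' sch <- default_schema()
#' sch$stages
#' @export
stage_schema <- function(stages,
                         optional = character(),
                         adult = utils::tail(stages, 2L),
                         female = adult[1L]) {
  stopifnot(is.character(stages), length(stages) >= 3L, !anyDuplicated(stages))
  if (stages[1L] != "EGG")
    stop("first stage must be 'EGG'")
  if (!all(adult %in% stages) || !identical(utils::tail(stages, length(adult)), adult))
    stop("adult stages must be the last stages of the schema")
  if (!female %in% adult)
    stop("female stage must be one of the adult stages")
  if (!all(optional %in% stages))
    stop("optional stages must be part of the schema")
  if (length(optional)) {
    idx <- match(optional, stages)
    if (any(diff(sort(idx)) != 1L))
      stop("optional stages must be contiguous")
    n_preadult <- length(stages) - length(adult)
    if (max(idx) >= n_preadult)  # must precede the pupal (last pre-adult) stage
      stop("optional stages must precede the pupal stage")
  }
  structure(list(stages = stages, optional = optional, adult = adult,
                 female = female, male = setdiff(adult, female),
                 beta = length(stages)),
            class = "stage_schema")
}

#' Default fall armyworm stage schema
#'
#' Egg, larval instars L1-L8 (L7 and L8 optional, i.e. supernumerary), pupa,
#' then adult female and adult male.
#'
#' @return A `stage_schema` with 12 stages.
#' @export
default_schema <- function() {
  stage_schema(c("EGG", paste0("L", 1:8), "PUPA", "ADULT_F", "ADULT_M"),
               optional = c("L7", "L8"))
}

#' @export
print.stage_schema <- function(x, ...) {
  cat("<stage_schema> ", paste(x$stages, collapse = " > "), "\n",
      "optional: ", if (length(x$optional)) paste(x$optional, collapse = ", ")
      else "(none)",
      " | female stage: ", x$female, "\n", sep = "")
  invisible(x)
}

stage_index <- function(schema, stage) match(stage, schema$stages)

# Stages of larval type (between EGG and PUPA), used for supernumerary counts.
larval_stages <- function(schema) {
  n_preadult <- schema$beta - length(schema$adult)
  schema$stages[2:(n_preadult - 1L)]
}

pupal_stage <- function(schema) schema$stages[schema$beta - length(schema$adult)]
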