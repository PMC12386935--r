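#' Water-loss-corrected leaf consumption
#'
#' In a feeding assay, leaf discs lose weight both to larval consumption and to
#' evaporation. With a control water-loss fraction c (measured on discs without
#' larvae over the same period), the consumption is
#' `before * (1 - c) - after`, floored at 0. If `after` exceeds the expected
#' residual by more than `tol`, a warning is raised and the value clamped to 0.
#'
#' @param before,after Disc weights (mg) before and after exposure.
#' @param control_loss_fraction Fraction of weight lost to evaporation alone,
#'   in `[0, 1)`.
#' @param tol Tolerance (mg) before the negative-consumption warning fires.
#' @return Consumption in mg (vectorised).
#' @export
corrected_consumption <- function(before, after, control_loss_fraction,
                                  tol = 1e-8) {
  stopifnot(all(before > 0), all(control_loss_fraction >= 0),
            all(control_loss_fraction < 1))
  raw <- before * (1 - control_loss_fraction) - after
  if (any(raw < -tol))
    warning(sum(raw < -tol),
            " measurement(s) with after-weight above the expected residual; ",
            "clamped to 0")
  pmax(raw, 0)
}

#' Read a bi-choice preference dataset
#'
#' Feeding files have columns
#' `replicate,species,weight_before_mg,weight_after_mg,control_loss_fraction`;
#' oviposition files have `replicate,plant,egg_batches`.
#'
#' @param path CSV file path.
#' @param mode `"feeding"` or `"oviposition"`.
#' @return An object of class `preference_dataset`: list with the raw
#'   `replicates` data.frame, `mode`, `choices` (choice labels) and `b`
#'   (number of replicates).
#' @export
read_preference <- function(path, mode = c("feeding", "oviposition")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- if (mode == "feeding")
    c("replicate", "species", "weight_before_mg", "weight_after_mg",
      "control_loss_fraction")
  else c("replicate", "plant", "egg_batches")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("preference format error: missing column(s): ",
         paste(miss, collapse = ", "))
  choice_col <- if (mode == "feeding") "species" else "plant"
  structure(list(replicates = d, mode = mode,
                 choices = sort(unique(d[[choice_col]])),
                 b = length(unique(d$replicate))),
            class = "preference_dataset")
}

#' Per-replicate preference proportions
#'
#' Feeding preference is the proportion of (water-loss-corrected) weight loss
#' per species relative to the replicate total; oviposition preference is the
#' proportion of egg batches per plant relative to the replicate total. Rows
#' sum to 1. Replicates with zero total are excluded (count reported in the
#' `"excluded"` attribute). For feeding data, `include = "both_consumed"`
#' additionally restricts to replicates where every choice was consumed.
#'
#' @param dataset A [read_preference()] result.
#' @param include `"all_nonzero"` (default: every replicate with a positive
#'   total) or `"both_consumed"` (feeding only: every choice consumed).
#' @return A b x k matrix of proportions with replicate ids as row names and an
#'   `"excluded"` attribute (number of dropped replicates).
#' @export
preference_proportions <- function(dataset,
                                   include = c("all_nonzero", "both_consumed")) {
  stopifnot(inherits(dataset, "preference_dataset"))
  include <- match.arg(include)
  d <- dataset$replicates
  if (dataset$mode == "feeding") {
    d$value <- corrected_consumption(d$weight_before_mg, d$weight_after_mg,
                                     d$control_loss_fraction)
    choice <- d$species
  } else {
    stopifnot(all(d$egg_batches >= 0))
    d$value <- d$egg_batches
    choice <- d$plant
  }
  wide <- tapply(d$value, list(factor(d$replicate),
                               factor(choice, levels = dataset$choices)), sum)
  wide[is.na(wide)] <- 0
  tot <- rowSums(wide)
  keep <- tot > 0
  if (include == "both_consumed") keep <- keep & apply(wide > 0, 1L, all)
  excluded <- sum(!keep)
  if (!any(keep)) stop("no usable replicates after exclusion")
  out <- wide[keep, , drop = FALSE] / tot[keep]
  attr(out, "excluded") <- excluded
  out
}

# Quade statistic machinery; `proportions` is a b x k matrix. Returns the
# building blocks so both the F approximation and the permutation fallback can
# share them. Within-block ranks and block-range ranks use mid-ranks for ties.
quade_parts <- function(proportions) {
  b <- nrow(proportions); k <- ncol(proportions)
  r <- t(apply(proportions, 1L, rank))                     # within-block ranks
  ranges <- apply(proportions, 1L, function(z) diff(range(z)))
  Q <- rank(ranges)                                        # ranked block ranges
  S <- Q * (r - (k + 1) / 2)
  A <- sum(S^2)
  Bstat <- sum(colSums(S)^2) / b
  list(b = b, k = k, S = S, Q = Q, A = A, B = Bstat)
}

quade_B_perm <- function(S0, Q) {
  # permutation distribution of the B statistic: within-block rank orderings
  # are equally likely under H0; S values within a block are a fixed multiset,
  # so permuting columns within each block spans the null.
  b <- nrow(S0); k <- ncol(S0)
  perms <- permutations_of(k)
  np <- nrow(perms)
  idx <- rep(1L, b)
  out <- numeric(np^b)
  colsum <- function(assign) {
    cs <- numeric(k)
    for (i in seq_len(b)) cs <- cs + S0[i, perms[assign[i], ]]
    sum(cs^2) / b
  }
  # mixed-radix enumeration over (k!)^b assignments
  for (t in seq_along(out)) {
    out[t] <- colsum(idx)
    j <- 1L
    while (j <= b) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L
      j <- j + 1L
    }
  }
  out
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (pos in seq_len(k)) for (s in seq_len(nrow(sub))) {
    perm <- integer(k)
    perm[pos] <- k
    perm[-pos] <- sub[s, ]
    out[row, ] <- perm
    row <- row + 1L
  }
  out
}

#' Quade randomized-block test
#'
#' Tests whether the k choices of a randomized complete block design differ,
#' weighting within-block ranks by the ranked block ranges (so blocks that
#' discriminate more strongly count more). Within-block ranks `r_ij` and block
#' range ranks `Q_i` use mid-ranks for ties;
#' `S_ij = Q_i (r_ij - (k+1)/2)`, `A = sum S_ij^2`,
#' `B = sum_j (sum_i S_ij)^2 / b`, and the statistic `(b-1) B / (A - B)` is
#' referred to the F distribution with `(k-1, (b-1)(k-1))` degrees of freedom.
#'
#' Degenerate cases: a constant matrix (all block ranges zero) yields p = 1
#' with a `degenerate` flag; perfect concordance (A = B, infinite statistic)
#' falls back to the exact permutation p-value when `(k!)^b` is enumerable and
#' to the closed form `2 * (1/k!)^(b-1)` otherwise, with a flag either way.
#'
#' @param proportions A b x k matrix (blocks x choices), e.g. from
#'   [preference_proportions()].
#' @param exact If `TRUE`, also compute the exact permutation p-value
#'   `P(B_perm >= B_obs)` by full enumeration (requires `(k!)^b <= 2^16`).
#' @return An object of class `quade_result`: `statistic`, `df1`, `df2`,
#'   `p.value`, flags `degenerate` and `concordant`, and `exact_p` when
#'   requested or used as fallback.
#' @export
quade_test <- function(proportions, exact = FALSE) {
  proportions <- as.matrix(proportions)
  b <- nrow(proportions); k <- ncol(proportions)
  stopifnot(b >= 2L, k >= 2L)
  qp <- quade_parts(proportions)
  df1 <- k - 1; df2 <- (b - 1) * (k - 1)
  res <- list(statistic = NA_real_, df1 = df1, df2 = df2, p.value = NA_real_,
              degenerate = FALSE, concordant = FALSE, exact_p = NA_real_)
  if (qp$A == 0) {                               # constant matrix
    res$degenerate <- TRUE
    res$statistic <- 0
    res$p.value <- 1
    return(structure(res, class = "quade_result"))
  }
  enumerable <- factorial(k)^b <= 2^16
  if (abs(qp$A - qp$B) < 1e-12 * qp$A) {         # perfect concordance
    res$concordant <- TRUE
    res$statistic <- Inf
    if (enumerable) {
      perm <- quade_B_perm(qp$S, qp$Q)
      res$exact_p <- mean(perm >= qp$B - 1e-12)
      res$p.value <- res$exact_p
    } else {
      res$p.value <- min(1, 2 * (1 / factorial(k))^(b - 1))
    }
    return(structure(res, class = "quade_result"))
  }
  res$statistic <- (b - 1) * qp$B / (qp$A - qp$B)
  res$p.value <- stats::pf(res$statistic, df1, df2, lower.tail = FALSE)
  if (exact) {
    if (!enumerable)
      stop("exact enumeration infeasible: (k!)^b too large")
    perm <- quade_B_perm(qp$S, qp$Q)
    res$exact_p <- mean(perm >= qp$B - 1e-12)
  }
  structure(res, class = "quade_result")
}

#' @export
print.quade_result <- function(x, ...) {
  cat(sprintf("<quade_result> F(%g, %g) = %.4g, p = %.4g%s%s\n",
              x$df1, x$df2, x$statistic, x$p.value,
              if (x$degenerate) " [degenerate: constant data]" else "",
              if (x$concordant) " [perfect concordance: permutation fallback]"
              else ""))
  if (is.finite(x$exact_p))
    cat(sprintf("  exact permutation p = %.6g\n", x$exact_p))
  invisible(x)
}
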