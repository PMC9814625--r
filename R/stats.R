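#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The exact permutation
#' distribution is used when `length(x) + length(y) <= 16` and there are no
#' ties; otherwise the tie-corrected normal approximation with continuity
#' correction applies. The U statistic reported is the number of (x, y)
#' pairs with x > y (plus half the ties), so `0 <= U <= n_x * n_y`.
#'
#' Two identical constant samples have zero rank variance; that degenerate
#' case is reported as `U = n_x n_y / 2`, `p = 1`.
#'
#' @param x,y Non-empty numeric vectors (the two groups' values).
#' @return List with `U` and two-sided `p`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) {
    cf_abort("both samples must be non-empty", "empty_sample")
  }
  nx <- length(x)
  ny <- length(y)
  ranks <- rank(c(x, y))
  U <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2

  ties <- anyDuplicated(c(x, y)) > 0
  if (ties && length(unique(c(x, y))) == 1L) {
    return(list(U = nx * ny / 2, p = 1))
  }
  exact <- (nx + ny <= 16) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  p <- wt$p.value
  if (is.na(p) || is.nan(p)) p <- 1
  list(U = unname(U), p = min(1, p))
}

#' Compare flux distributions between groups
#'
#' For each requested reaction, pools the case rows against the control rows
#' of the feature table (or, optionally, one mean flux per patient) and
#' applies [mann_whitney_u()]. Significance is called on the raw p-value at
#' `alpha`; Benjamini-Hochberg adjusted p-values are reported alongside as a
#' supplementary column.
#'
#' @param features A `feature_table` from [assemble_feature_matrix()].
#' @param reactions Reaction ids to test (subset of the feature order).
#' @param alpha Raw-p significance level (default 0.05).
#' @param mode `"pooled"` pools all flux points of a group;
#'   `"patient_mean"` first averages each patient's points.
#' @return Data frame with one row per reaction: `U`, `p_value`,
#'   `p_adjusted` (BH), group medians, group sizes, and `significant`.
#' @export
compare_groups <- function(features, reactions, alpha = 0.05,
                           mode = c("pooled", "patient_mean")) {
  stopifnot(inherits(features, "feature_table"))
  mode <- match.arg(mode)
  unknown <- setdiff(reactions, features$features)
  if (length(unknown)) {
    cf_abort(sprintf("unknown reaction: %s", unknown[1]), "unknown_reaction")
  }

  value_sets <- lapply(reactions, function(r) {
    v <- features$x[, r]
    if (mode == "patient_mean") {
      per_pat <- tapply(v, features$row_patient, mean)
      grp <- features$patients[names(per_pat)]
      list(case = unname(per_pat[grp == "case"]),
           control = unname(per_pat[grp == "control"]))
    } else {
      list(case = v[features$row_group == "case"],
           control = v[features$row_group == "control"])
    }
  })

  rows <- lapply(seq_along(reactions), function(i) {
    vs <- value_sets[[i]]
    mw <- mann_whitney_u(vs$case, vs$control)
    data.frame(
      reaction = reactions[i],
      U = mw$U,
      p_value = mw$p,
      median_case = stats::median(vs$case),
      median_control = stats::median(vs$control),
      n_case = length(vs$case),
      n_control = length(vs$control),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Group reactions into subsystem families
#'
#' Assigns each reaction to a family: an explicit override label wins,
#' otherwise the model's subsystem annotation is used, and reactions with
#' neither go to `"Unassigned"`. Mirrors the practice of grouping
#' discriminative reactions by their curated pathway (subsystem) membership.
#'
#' @param reactions Character vector of reaction ids.
#' @param network A [metabolic_network()] carrying subsystem annotations.
#' @param override Optional named character vector (reaction id -> family).
#' @return Named list: family label -> reaction ids (non-empty families
#'   only; empty input gives an empty list).
#' @export
group_by_subsystem <- function(reactions, network, override = NULL) {
  if (!length(reactions)) return(stats::setNames(list(), character()))
  fam <- vapply(reactions, function(r) {
    if (!is.null(override) && r %in% names(override)) {
      return(override[[r]])
    }
    s <- network$subsystem[r]
    if (!is.na(s) && nzchar(s)) unname(s) else "Unassigned"
  }, character(1))
  split(unname(reactions), fam)
}
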