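#' Chi-squared agreement between automated and human visualization counts
#'
#' Goodness-of-fit of the algorithm's count-category frequencies against the
#' human count distribution: categories are the union of counts observed in
#' either list, expected frequencies are the human proportions scaled to n,
#' and categories with zero expected frequency are pooled into the nearest
#' (by count value) category with positive expectation. The per-figure
#' exact-match rate is reported alongside, since the test compares marginal
#' distributions, not paired values.
#'
#' @param algo_counts,human_counts Equal-length integer vectors of
#'   per-figure visualization counts (>= 1).
#' @return List with `statistic`, `df`, `p_value` and `exact_match_rate`.
#'   If every figure falls in a single category the statistic is 0 with
#'   df 0 and the p-value is reported as 1 with a warning.
#' @export
count_agreement_chisq <- function(algo_counts, human_counts) {
  a <- as.integer(algo_counts); h <- as.integer(human_counts)
  if (length(a) != length(h)) stop_medvis("count lists must have equal length")
  if (length(a) < 2L) stop_medvis("need at least 2 figures")
  if (any(a < 1L) || any(h < 1L)) stop_medvis("counts must be >= 1")
  n <- length(a)

  cats <- sort(union(a, h))
  obs <- as.numeric(table(factor(a, levels = cats)))
  expd <- as.numeric(table(factor(h, levels = cats))) / n * n

  if (length(cats) == 1L) {
    warning("all figures fall in one count category; chi-squared undefined",
            call. = FALSE)
    return(list(statistic = 0, df = 0L, p_value = 1,
                exact_match_rate = mean(a == h)))
  }

  # pool zero-expected categories into the nearest positive-expectation one
  zero <- which(expd == 0)
  if (length(zero)) {
    pos <- which(expd > 0)
    for (i in zero) {
      j <- pos[which.min(abs(cats[pos] - cats[i]))]
      obs[j] <- obs[j] + obs[i]
      expd[j] <- expd[j] + expd[i]
    }
    obs <- obs[-zero]; expd <- expd[-zero]
  }

  stat <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1L
  p <- if (df >= 1L) stats::pchisq(stat, df, lower.tail = FALSE) else {
    warning("single pooled category; chi-squared undefined", call. = FALSE)
    1
  }
  list(statistic = stat, df = df, p_value = p,
       exact_match_rate = mean(a == h))
}

#' Agreement between algorithm labels and human majority votes
#'
#' Per figure, the human consensus is the majority vote with the proportion
#' of Good votes compared against a 0.5 decision threshold (a proportion of
#' exactly 0.5 counts as Good). Produces the confusion matrix over
#' good/not_good, accuracy, per-class precision and recall, and the
#' per-figure vote-proportion table used for lollipop-style agreement plots.
#'
#' @param algo_labels Named character vector (`figure_id` -> `"good"` /
#'   `"not_good"`), e.g. from a fitted [medvis()] object.
#' @param human_votes Named list: `figure_id` -> character vector of votes in
#'   `c("Good", "Bad")`, one element per rater.
#' @return Object of class `agreement_report`: list with `confusion`
#'   (2 x 2 matrix, rows = human, cols = algorithm), `accuracy`,
#'   `precision` and `recall` (named by class), and `per_figure` (data frame
#'   with `figure_id`, `prop_good`, `human_label`, `algo_label`, `agree`).
#' @export
label_agreement_report <- function(algo_labels, human_votes) {
  ids <- intersect(names(algo_labels), names(human_votes))
  if (length(ids) == 0L) stop_medvis("no co-rated figures")
  n_votes <- vapply(human_votes[ids], length, integer(1))
  if (any(n_votes == 0L))
    stop_medvis("figure with no votes: ",
                paste(ids[n_votes == 0L], collapse = ", "))
  bad_vote <- vapply(human_votes[ids],
                     function(v) !all(v %in% c("Good", "Bad")), logical(1))
  if (any(bad_vote)) stop_medvis("votes must be 'Good' or 'Bad'")

  ids <- sort(ids, method = "radix")
  prop_good <- vapply(human_votes[ids], function(v) mean(v == "Good"),
                      numeric(1))
  human <- ifelse(prop_good >= 0.5, "good", "not_good")
  algo <- unname(algo_labels[ids])
  if (!all(algo %in% c("good", "not_good")))
    stop_medvis("algo labels must be 'good' or 'not_good'")

  lv <- c("good", "not_good")
  confusion <- table(human = factor(human, lv), algo = factor(algo, lv))
  confusion <- unclass(confusion)
  acc <- sum(diag(confusion)) / length(ids)
  precision <- vapply(lv, function(cl) {
    denom <- sum(confusion[, cl])
    if (denom == 0) NA_real_ else confusion[cl, cl] / denom
  }, numeric(1))
  recall <- vapply(lv, function(cl) {
    denom <- sum(confusion[cl, ])
    if (denom == 0) NA_real_ else confusion[cl, cl] / denom
  }, numeric(1))

  structure(list(
    confusion = confusion,
    accuracy = acc,
    precision = precision,
    recall = recall,
    per_figure = data.frame(
      figure_id = ids,
      prop_good = unname(prop_good),
      human_label = unname(human),
      algo_label = algo,
      agree = unname(human == algo),
      stringsAsFactors = FALSE
    )
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>", nrow(x$per_figure), "co-rated figures\n")
  cat(sprintf("  accuracy: %.3f\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}
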