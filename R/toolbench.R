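#' Load the packaged visualization-tool benchmark table
#'
#' A reference comparison of 26 widely used data-visualization tools, rated
#' on a 5-point scale (higher is better) for ease of use and customizability,
#' with financial cost kept as the original categorical tier strings (e.g.
#' "Free", "1", "Requires a quote") and the background knowledge each tool
#' assumes.
#'
#' @return Data frame with columns `name`, `financial_cost`,
#'   `required_knowledge`, `ease_of_use`, `customizability`, in the
#'   published order.
#' @export
load_tool_table <- function() {
  path <- system.file("extdata", "tool_benchmark.csv", package = "medvis",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("name", "financial_cost", "required_knowledge",
                "ease_of_use", "customizability")
  if (!identical(names(tab), expected) ||
      !all(tab$ease_of_use %in% 1:5) ||
      !all(tab$customizability %in% 1:5))
    stop_medvis("packaged tool benchmark table is corrupt")
  tab
}

#' Summarize the tool benchmark table
#'
#' Applies a user-supplied filter predicate to the tool records and returns
#' the requested statistic of one of the score columns. Which tools count as
#' e.g. "coding-based" is deliberately left to the caller's predicate.
#'
#' @param tools Data frame from [load_tool_table()] (default loads it).
#' @param filter Predicate function taking the data frame and returning a
#'   logical vector, or `NULL` for all rows.
#' @param statistic `"median"`, `"mean"` or `"count"`.
#' @param column Score column, `"ease_of_use"` or `"customizability"`.
#' @return A single number; for an empty filter result, `count` is 0 and the
#'   other statistics are `NA` (undefined on an empty set).
#' @export
summarize_tools <- function(tools = load_tool_table(), filter = NULL,
                            statistic = c("median", "mean", "count"),
                            column = c("customizability", "ease_of_use")) {
  statistic <- match.arg(statistic)
  column <- match.arg(column)
  keep <- if (is.null(filter)) rep(TRUE, nrow(tools)) else filter(tools)
  stopifnot(is.logical(keep), length(keep) == nrow(tools))
  sel <- tools[[column]][keep & !is.na(keep)]
  switch(statistic,
         count = length(sel),
         median = if (length(sel)) stats::median(sel) else NA_real_,
         mean = if (length(sel)) mean(sel) else NA_real_)
}
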