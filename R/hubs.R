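## Connector / provincial hub classification from sample-aggregated nodal
## metrics.

#' Classify connector and provincial hubs
#'
#' Connector hubs are regions with betweenness centrality and participation
#' coefficient both strictly above the `pct`-th percentile of regions;
#' provincial hubs have within-module degree z strictly above and
#' participation strictly below that percentile. Percentiles use linear
#' interpolation; values tied with the cut are excluded from "above" sets, so
#' the two hub types are disjoint by construction.
#'
#' @param nodal data.frame of sample-aggregated nodal metrics (typically the
#'   mean of per-subject [nodalMetrics()] tables over included subjects) with
#'   columns region_id, betweenness, participation, within_module_z.
#' @param pct Percentile cut (default 70).
#' @return list with `connector` and `provincial` region id vectors, `pct`,
#'   and `cuts` (the three percentile values used).
#' @export
classifyHubs <- function(nodal, pct = 70) {
  need <- c("region_id", "betweenness", "participation", "within_module_z")
  stopifnot(all(need %in% names(nodal)))
  for (v in need[-1]) {
    if (stats::sd(nodal[[v]]) == 0)
      stop(sprintf("metric '%s' is constant across regions; percentile rules are degenerate", v))
  }
  cutB <- pctile(nodal$betweenness, pct)
  cutP <- pctile(nodal$participation, pct)
  cutZ <- pctile(nodal$within_module_z, pct)
  connector <- nodal$region_id[nodal$betweenness > cutB & nodal$participation > cutP]
  provincial <- nodal$region_id[nodal$within_module_z > cutZ & nodal$participation < cutP]
  list(connector = connector, provincial = provincial, pct = pct,
       cuts = c(betweenness = cutB, participation = cutP, within_module_z = cutZ))
}

#' Aggregate per-subject nodal metrics across a sample
#'
#' Mean of each nodal metric over subjects, region by region: the basis on
#' which one hub set is defined for the whole sample.
#'
#' @param nodalList List of per-subject [nodalMetrics()] data.frames with
#'   identical region order.
#' @return data.frame in the same layout with metrics averaged.
#' @export
aggregateNodalMetrics <- function(nodalList) {
  stopifnot(length(nodalList) >= 1L)
  ref <- nodalList[[1L]]
  metricCols <- setdiff(names(ref), "region_id")
  acc <- Reduce(`+`, lapply(nodalList, function(d) as.matrix(d[, metricCols])))
  out <- data.frame(region_id = ref$region_id,
                    acc / length(nodalList), row.names = NULL)
  names(out) <- c("region_id", metricCols)
  out
}
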