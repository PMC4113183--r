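#' Replicate-pool design
#'
#' Builds the pool layout of the experiment: every combination of line
#' (default HA/LA) and condition (default sham/SNL) with `replicates`
#' biological replicate pools each. Pool identifiers follow the
#' `<line>_<condition><replicate>` convention (e.g. `HA_SNL1`).
#'
#' @param lines Character vector of line labels (two contrasting lines).
#' @param conditions Character vector of condition labels; the second is
#'   treated as the injury condition by the regulation statistics.
#' @param replicates Integer, replicate pools per line x condition group
#'   (must be >= 2; the pairwise diff-reg estimator needs at least two
#'   pools per group).
#' @return A [S4Vectors::DataFrame] with columns `pool`, `line`,
#'   `condition`, `replicate` and `group`, one row per pool.
#' @examples
#' poolDesign()                 # the 12-pool layout
#' poolDesign(replicates = 2)   # a reduced 8-pool layout
#' @export
poolDesign <- function(lines = c("HA", "LA"),
                       conditions = c("sham", "SNL"),
                       replicates = 3L) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 2L)
    stop("'replicates' must be an integer >= 2")
  if (length(lines) < 1L || length(conditions) < 2L)
    stop("need at least one line and two conditions")
  if (anyDuplicated(lines) || anyDuplicated(conditions))
    stop("line and condition labels must be unique")
  grid <- expand.grid(replicate = seq_len(replicates),
                      condition = conditions, line = lines,
                      stringsAsFactors = FALSE)
  d <- DataFrame(
    pool = paste0(grid$line, "_", grid$condition, grid$replicate),
    line = grid$line,
    condition = grid$condition,
    replicate = grid$replicate,
    group = paste0(grid$line, "_", grid$condition)
  )
  rownames(d) <- d$pool
  d
}

## group label of each pool id under a design
.groupOf <- function(design, pools) {
  design$group[match(pools, design$pool)]
}

.checkDesign <- function(design) {
  need <- c("pool", "line", "condition", "replicate", "group")
  if (!all(need %in% colnames(design)))
    stop("design must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(design$pool)) stop("pool ids must be unique")
  if (any(table(design$group) < 1L)) stop("every group must be non-empty")
  invisible(design)
}
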