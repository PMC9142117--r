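#' Per-quintile descriptive statistics
#'
#' Mean (SD) of every covariate, and optionally of each condition's visit
#' rate, within each LTU quintile — the standard descriptive table for this
#' design.
#'
#' @param zctas ZCTA covariate table.
#' @param assignments data.frame with `zcta_id` and `quintile`.
#' @param panel optional `rate_panel`; when given, per-condition rates are
#'   appended as rows.
#' @return data.frame with `variable`, then `q1_mean`..`q5_mean` and
#'   `q1_sd`..`q5_sd`.
#' @export
quintile_descriptives <- function(zctas, assignments, panel = NULL) {
  q <- assignments$quintile[match(zctas$zcta_id, assignments$zcta_id)]
  if (anyNA(q))
    stop_input("quintile_descriptives: unassigned ZCTA '%s'",
               zctas$zcta_id[which(is.na(q))[1]])
  vars <- setdiff(names(zctas), c("zcta_id", "pop_year1", "pop_year2"))
  blocks <- lapply(vars, function(nm) {
    data.frame(variable = nm,
               t(tapply(zctas[[nm]], factor(q, levels = 1:5), mean)),
               t(tapply(zctas[[nm]], factor(q, levels = 1:5), stats::sd)))
  })
  if (!is.null(panel)) {
    qr_ <- assignments$quintile[match(rownames(panel$rates), assignments$zcta_id)]
    rate_blocks <- lapply(panel$conditions, function(cond) {
      r <- panel$rates[, cond]
      data.frame(variable = paste0("rate: ", cond),
                 t(tapply(r, factor(qr_, levels = 1:5), mean)),
                 t(tapply(r, factor(qr_, levels = 1:5), stats::sd)))
    })
    blocks <- c(blocks, rate_blocks)
  }
  out <- do.call(rbind, blocks)
  names(out) <- c("variable", paste0("q", 1:5, "_mean"), paste0("q", 1:5, "_sd"))
  rownames(out) <- NULL
  out
}
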