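# ED encounter processing: inclusion filters, condition tabulation, and
# two-year visit rates per 1000 population.

#' Filter ED encounters to the analytic sample
#'
#' Keeps encounters by uninsured patients (payer self-pay or
#' indigent/charitable), aged 18-64, with a billing area present in
#' `valid_zctas`. Every input record is attributed exactly once: records with
#' unparseable fields (missing or unknown payer, missing age, missing area)
#' go to an `unparseable` bucket; the remainder are tested in the fixed order
#' payer, then age, then area, and an excluded record is attributed to the
#' first criterion it fails.
#'
#' @param records data.frame of encounters with columns `zcta_id`, `age`,
#'   `payer` (and typically `encounter_id`, `condition`, `year`).
#' @param valid_zctas character vector of valid area labels.
#' @return list with `records` (the kept rows) and `tally`, an object of
#'   class `filter_tally` with fields `input`, `kept`, `payer`, `age`,
#'   `area`, `unparseable`.
#' @export
filter_encounters <- function(records, valid_zctas) {
  if (length(valid_zctas) == 0L)
    stop_input("filter_encounters: 'valid_zctas' is empty")
  need <- c("zcta_id", "age", "payer")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop_input("filter_encounters: missing column(s): %s",
               paste(missing, collapse = ", "))

  n <- nrow(records)
  unparseable <- is.na(records$payer) | !(records$payer %in% payer_levels()) |
    is.na(records$age) | is.na(records$zcta_id)
  fail_payer <- !unparseable & !(records$payer %in% uninsured_payers())
  fail_age <- !unparseable & !fail_payer &
    (records$age < 18 | records$age > 64)
  fail_area <- !unparseable & !fail_payer & !fail_age &
    !(records$zcta_id %in% valid_zctas)
  keep <- !unparseable & !fail_payer & !fail_age & !fail_area

  tally <- structure(
    list(input = n, kept = sum(keep), payer = sum(fail_payer),
         age = sum(fail_age), area = sum(fail_area),
         unparseable = sum(unparseable)),
    class = "filter_tally"
  )
  list(records = records[keep, , drop = FALSE], tally = tally)
}

#' @export
print.filter_tally <- function(x, ...) {
  cat(sprintf("Encounter filter: %d in, %d kept\n", x$input, x$kept))
  cat(sprintf("  excluded - payer: %d, age: %d, area: %d, unparseable: %d\n",
              x$payer, x$age, x$area, x$unparseable))
  invisible(x)
}

#' Tabulate the most frequent conditions
#'
#' Counts filtered encounters by minor diagnostic category and returns the
#' `k` most frequent, ties broken by label (ascending).
#'
#' @param records filtered encounter data.frame with a `condition` column.
#' @param k number of conditions to keep (default 15).
#' @return data.frame with `condition` and `count`, most frequent first.
#' @export
tabulate_conditions <- function(records, k = 15L) {
  if (!is_count(k) || k < 1L)
    stop_input("tabulate_conditions: 'k' must be a positive integer")
  tab <- table(records$condition)
  out <- data.frame(condition = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$condition), , drop = FALSE]
  if (nrow(out) < k)
    warning(sprintf("tabulate_conditions: only %d distinct conditions (k = %d)",
                    nrow(out), k), call. = FALSE)
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Compute two-year visit rates per 1000 population
#'
#' For every (ZCTA, condition) pair: `rate = 1000 x count / (pop_year1 +
#' pop_year2)`. The panel is dense: pairs with no visits get count 0 and
#' rate 0, so every area contributes a row to each condition's regression.
#'
#' @param records filtered encounter data.frame (`zcta_id`, `condition`).
#' @param zctas ZCTA table with `zcta_id`, `pop_year1`, `pop_year2`.
#' @param conditions character vector of conditions to include (e.g. from
#'   [tabulate_conditions()]).
#' @return object of class `rate_panel`: long data.frame `long` with
#'   `zcta_id`, `condition`, `count`, `rate`; plus `conditions`, `pop2`
#'   (named two-year populations) and matrix accessors via [rate_matrix()].
#' @export
compute_rates <- function(records, zctas, conditions) {
  if (length(conditions) == 0L)
    stop_input("compute_rates: empty condition list")
  pop2 <- zctas$pop_year1 + zctas$pop_year2
  bad <- which(!(pop2 > 0))
  if (length(bad))
    stop_input("compute_rates: nonpositive two-year population for ZCTA '%s'",
               zctas$zcta_id[bad[1]])
  names(pop2) <- zctas$zcta_id
  unknown <- setdiff(unique(records$zcta_id), zctas$zcta_id)
  if (length(unknown))
    stop_input("compute_rates: record ZCTA '%s' absent from the ZCTA table",
               unknown[1])

  sub <- records[records$condition %in% conditions, , drop = FALSE]
  counts <- table(factor(sub$zcta_id, levels = zctas$zcta_id),
                  factor(sub$condition, levels = conditions))
  counts <- matrix(as.integer(counts), nrow = nrow(zctas),
                   dimnames = list(zctas$zcta_id, conditions))
  rates <- 1000 * counts / pop2

  long <- data.frame(
    zcta_id = rep(zctas$zcta_id, times = length(conditions)),
    condition = rep(conditions, each = nrow(zctas)),
    count = as.vector(counts),
    rate = as.vector(rates),
    stringsAsFactors = FALSE
  )
  structure(list(long = long, conditions = conditions, pop2 = pop2,
                 counts = counts, rates = rates),
            class = "rate_panel")
}

#' Extract the ZCTA x condition rate (or count) matrix from a panel
#'
#' @param panel a `rate_panel`.
#' @param what `"rate"` (default) or `"count"`.
#' @return numeric matrix, rows = ZCTAs, columns = conditions.
#' @export
rate_matrix <- function(panel, what = c("rate", "count")) {
  what <- match.arg(what)
  if (!inherits(panel, "rate_panel"))
    stop_input("rate_matrix: 'panel' must be a rate_panel")
  if (what == "rate") panel$rates else panel$counts
}

#' @export
print.rate_panel <- function(x, ...) {
  cat(sprintf("Rate panel: %d ZCTAs x %d conditions, %d visits total\n",
              length(x$pop2), length(x$conditions), sum(x$counts)))
  cat(sprintf("  mean rate per 1000 (two-year): %.2f\n", mean(x$rates)))
  invisible(x)
}
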