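#' @title 2x2 contingency tables per MedDRA term
#' @description Builds the a/b/c/d counts underlying every disproportionality
#'   statistic. The counting unit is the distinct (case, PT) pair: a case
#'   reporting k distinct Preferred Terms contributes k pairs, but a PT
#'   mentioned twice within one case counts once. System Organ Class tables
#'   are cumulative sums of their member-PT pair counts.
#' @name contingency
NULL

#' Build per-PT 2x2 contingency tables for a target drug
#'
#' For each Preferred Term observed anywhere in the store:
#' `a` = target-case pairs with the term, `b` = target-case pairs with other
#' terms, `c` = background pairs with the term, `d` = background pairs with
#' other terms. Background is every deduplicated case not in the target set
#' (a case carrying the target drug in a non-primary-suspect role counts as
#' background).
#'
#' @param store a deduplicated `faers_store`.
#' @param target_case_ids case identifiers from [select_primary_suspect()].
#' @return data.frame (class `contingency_tables`) with columns `term`,
#'   `level`, `a`, `b`, `c`, `d`; margins `a + b` and `c + d` are constant
#'   across rows.
#' @export
build_pt_tables <- function(store, target_case_ids) {
  stopifnot(inherits(store, "faers_store"))
  if (length(target_case_ids) == 0L) {
    stop("no target reports", call. = FALSE)
  }
  pairs <- unique(store$reac[, c("case_id", "pt")])
  is_target <- pairs$case_id %in% target_case_ids
  total_target <- sum(is_target)
  total_background <- sum(!is_target)
  pts <- sort(unique(pairs$pt))
  a <- as.integer(table(factor(pairs$pt[is_target], levels = pts)))
  ct <- as.integer(table(factor(pairs$pt[!is_target], levels = pts)))
  out <- data.frame(term = pts, level = "PT",
                    a = a, b = total_target - a,
                    c = ct, d = total_background - ct,
                    stringsAsFactors = FALSE)
  class(out) <- c("contingency_tables", "data.frame")
  out
}

#' Read a two-column PT-to-SOC mapping
#'
#' @param path CSV with columns `pt`, `soc`.
#' @return data.frame mapping each Preferred Term to one System Organ Class.
#' @export
read_pt_soc_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pt", "soc") %in% names(map))) {
    stop("PT->SOC map needs columns 'pt' and 'soc'", call. = FALSE)
  }
  map[, c("pt", "soc")]
}

#' Aggregate PT-level tables to System Organ Class level
#'
#' Per SOC, `a` and `c` are sums of the member PTs' pair counts (cumulative
#' occurrences: a case reporting three PTs of one SOC contributes three), and
#' `b`, `d` are recomputed from the fixed margins `a + b`, `c + d`. Every PT
#' must be mapped; unmapped PTs raise an error that lists them.
#'
#' @param pt_tables output of [build_pt_tables()].
#' @param pt_soc_map data.frame with columns `pt`, `soc`
#'   (see [read_pt_soc_map()]).
#' @return SOC-level `contingency_tables` data.frame.
#' @export
aggregate_soc <- function(pt_tables, pt_soc_map) {
  stopifnot(is.data.frame(pt_tables), is.data.frame(pt_soc_map))
  soc <- pt_soc_map$soc[match(pt_tables$term, pt_soc_map$pt)]
  if (anyNA(soc)) {
    stop("unmapped PTs: ",
         paste(sort(unique(pt_tables$term[is.na(soc)])), collapse = ", "),
         call. = FALSE)
  }
  margin_target <- if (nrow(pt_tables)) pt_tables$a[1] + pt_tables$b[1] else 0L
  margin_background <-
    if (nrow(pt_tables)) pt_tables$c[1] + pt_tables$d[1] else 0L
  a <- tapply(pt_tables$a, soc, sum)
  cc <- tapply(pt_tables$c, soc, sum)
  socs <- sort(names(a))
  out <- data.frame(term = socs, level = "SOC",
                    a = as.integer(a[socs]),
                    b = margin_target - as.integer(a[socs]),
                    c = as.integer(cc[socs]),
                    d = margin_background - as.integer(cc[socs]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contingency_tables", "data.frame")
  out
}
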