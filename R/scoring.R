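POUCH_SCORE <- c(normal = 1, misshapen = 1, reduced_gt50 = 0, missing = 0)
CB_SCORE <- c(normal = 1.0, reduced = 0.5, absent = 0)

#' Score a pouch state on the 0/1 rubric
#'
#' Pouches that are missing or reduced by more than half relative to wild
#' type score 0; mis-shapen or normal pouches score 1.  A wild-type side
#' (five normal pouches) therefore totals 5.
#'
#' @param state Character vector of states among `normal`, `misshapen`,
#'   `reduced_gt50`, `missing`.
#' @return Integer vector of 0/1 scores.
#' @export
score_pouch_state <- function(state) {
  if (!all(state %in% names(POUCH_SCORE))) {
    bad <- setdiff(unique(state), names(POUCH_SCORE))
    input_error(sprintf("unknown pouch state '%s'", bad[1]))
  }
  as.integer(unname(POUCH_SCORE[state]))
}

#' Score the ceratobranchial elements of one side
#'
#' Rubric: normal element 1.0, reduced 0.5, absent 0; a fusion of two
#' adjacent elements scores 1.5 in total (the fused pair's two positions
#' contribute only the 1.5, not their individual scores).  Five normal
#' elements with no fusion give the wild-type total of 5.0; one fused pair
#' plus three normals give 4.5.
#'
#' @param cb_elements Character vector of 5 states among `normal`,
#'   `reduced`, `absent` (positions cb1-cb5, anterior to posterior).
#' @param fused_pairs List of integer pairs `c(i, i + 1)` of adjacent
#'   positions marked fused; pairs may not share a position.
#' @return Per-side total on the 0.5 grid, between 0 and 5.
#' @export
score_cb_elements <- function(cb_elements, fused_pairs = list()) {
  if (length(cb_elements) != 5L || !all(cb_elements %in% names(CB_SCORE))) {
    input_error("cb_elements must be 5 states among normal/reduced/absent")
  }
  fused_pos <- integer(0)
  for (pair in fused_pairs) {
    if (length(pair) != 2L || abs(diff(pair)) != 1L ||
        any(pair < 1L) || any(pair > 5L)) {
      input_error("each fused pair must be two adjacent positions in 1..5")
    }
    if (any(pair %in% fused_pos)) {
      input_error("fused pairs overlap at a shared position")
    }
    fused_pos <- c(fused_pos, as.integer(pair))
  }
  free <- setdiff(1:5, fused_pos)
  sum(CB_SCORE[cb_elements[free]]) + 1.5 * length(fused_pairs)
}

#' Score one phenotype record (one embryo side)
#'
#' @param record A list (or one-row data frame in the phenotype-table
#'   dialect) with pouch states `p1`..`p5`, CB states `cb1`..`cb5`, and
#'   `fusions` (either a list of pairs or the `"2-3;4-5"` string encoding).
#' @return Named numeric vector `c(pouch_score, cb_score)`.
#' @examples
#' wt <- c(as.list(setNames(rep("normal", 5), paste0("p", 1:5))),
#'         as.list(setNames(rep("normal", 5), paste0("cb", 1:5))),
#'         list(fusions = ""))
#' score_record(wt) # 5, 5.0
#' @export
score_record <- function(record) {
  record <- as.list(record)
  pouch <- unlist(record[paste0("p", 1:5)], use.names = FALSE)
  cb <- unlist(record[paste0("cb", 1:5)], use.names = FALSE)
  if (length(pouch) != 5L || length(cb) != 5L) {
    input_error("record needs pouch states p1..p5 and CB states cb1..cb5")
  }
  fusions <- record$fusions
  if (is.null(fusions)) fusions <- list()
  if (is.character(fusions)) fusions <- parse_fusions(fusions)
  c(pouch_score = sum(score_pouch_state(pouch)),
    cb_score = score_cb_elements(cb, fusions))
}

# "2-3;4-5" -> list(c(2,3), c(4,5)); "" -> list()
parse_fusions <- function(s) {
  if (length(s) != 1L || is.na(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(p) {
    v <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
    if (length(v) != 2L || anyNA(v)) {
      input_error(sprintf("malformed fusion encoding '%s'", p))
    }
    v
  })
}

format_fusions <- function(pairs) {
  paste(vapply(pairs, function(p) sprintf("%d-%d", p[1], p[2]), character(1)),
        collapse = ";")
}

#' Score every record of a phenotype table
#'
#' @param records Phenotype table (see [simulate_phenotypes()] for the
#'   dialect).
#' @return Data frame `embryo_id`, `genotype`, `side`, `pouch_score`,
#'   `cb_score`.
#' @export
score_phenotypes <- function(records) {
  need <- c("embryo_id", "genotype", "side", paste0("p", 1:5), paste0("cb", 1:5))
  if (!all(need %in% names(records))) {
    input_error("phenotype table is missing required columns")
  }
  scores <- t(vapply(seq_len(nrow(records)),
                     function(i) score_record(records[i, , drop = FALSE]),
                     numeric(2)))
  data.frame(embryo_id = records$embryo_id, genotype = records$genotype,
             side = records$side, pouch_score = scores[, 1],
             cb_score = scores[, 2], stringsAsFactors = FALSE)
}

#' Per-genotype score summaries (mean, s.e.m., n)
#'
#' Scores each record and summarizes per genotype and metric.  By default
#' the embryo is the unit of analysis: when both sides of an embryo are
#' present their scores are averaged per embryo before the group summary,
#' matching figure-style ns that count embryos.  `unit = "side"` treats
#' every side as an observation instead.
#'
#' @param records Phenotype table.
#' @param unit `"embryo"` (default) or `"side"`.
#' @return Data frame `genotype`, `metric` (`pouch_score` / `cb_score`),
#'   `n`, `mean`, `sem`.
#' @export
summarize_scores <- function(records, unit = c("embryo", "side")) {
  unit <- match.arg(unit)
  scored <- score_phenotypes(records)
  if (unit == "embryo") {
    scored <- stats::aggregate(
      cbind(pouch_score, cb_score) ~ embryo_id + genotype, data = scored,
      FUN = mean)
  }
  rows <- list()
  for (g in unique(scored$genotype)) {
    sub <- scored[scored$genotype == g, ]
    for (m in c("pouch_score", "cb_score")) {
      v <- sub[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, metric = m, n = length(v), mean = mean(v),
        sem = if (length(v) >= 2L) sem(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
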