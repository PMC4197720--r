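POUCH_STATES <- c("normal", "misshapen", "reduced_gt50", "missing")
CB_STATES <- c("normal", "reduced", "absent")

#' Per-class parameters of the phenotype-record generator
#'
#' Each genotype class is described by categorical state distributions for
#' the five pharyngeal pouches (p1-p5) and the five ceratobranchial (CB)
#' cartilage elements per side, plus a probability that an adjacent pair of
#' surviving (normal) CBs is fused.
#'
#' @param class_name Genotype-class label.
#' @param pouch_probs 5 x 4 numeric matrix; rows p1-p5, columns the pouch
#'   states `normal`, `misshapen`, `reduced_gt50`, `missing`.  Each row must
#'   sum to 1 (tolerance 1e-12).
#' @param cb_probs 5 x 3 numeric matrix; rows cb1-cb5, columns `normal`,
#'   `reduced`, `absent`.  Each row must sum to 1.
#' @param fusion_prob Probability that an adjacent pair of normal CB
#'   elements is fused (scanned anterior to posterior; a fused element
#'   cannot join a second pair).
#' @param seed Integer seed used by [simulate_phenotypes()].
#' @return An object of class `phenotype_class_params`.
#' @seealso [phenotype_class()] for the shipped genotype classes.
#' @export
phenotype_class_params <- function(class_name, pouch_probs, cb_probs,
                                   fusion_prob = 0, seed = 1L) {
  if (!is.character(class_name) || length(class_name) != 1L || !nzchar(class_name)) {
    config_error("class_name", "must be a non-empty string")
  }
  check_prob_matrix(pouch_probs, "pouch_probs", POUCH_STATES)
  check_prob_matrix(cb_probs, "cb_probs", CB_STATES)
  check_scalar_number(fusion_prob, "fusion_prob", lower = 0, upper = 1)
  check_scalar_number(seed, "seed")
  structure(
    list(class_name = class_name, pouch_probs = pouch_probs,
         cb_probs = cb_probs, fusion_prob = fusion_prob,
         seed = as.integer(seed)),
    class = "phenotype_class_params"
  )
}

check_prob_matrix <- function(m, field, state_names) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != 5L ||
      ncol(m) != length(state_names)) {
    config_error(field, sprintf("must be a numeric 5 x %d matrix",
                                length(state_names)))
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
    config_error(field, "rows must be probability vectors summing to 1")
  }
  invisible(m)
}

#' Shipped genotype classes for the phenotype generator
#'
#' Returns the parameter bundle for one of the four default genotype
#' classes.  The classes encode the printed group descriptions:
#'
#' * `wild_type` — all five pouches and CBs normal with probability 1
#'   (wild types invariantly show five of each per side).
#' * `tbx1` — only p1 forms; p2-p5 missing and all CBs absent.
#' * `single_mutant` — p1 normal; p2-p5 each normal with probability 0.75
#'   else missing (expected pouch score 1 + 4 x 0.75 = 4); CBs analogous,
#'   targeting a mean CB score of 4.
#' * `double_mutant` — p1 normal; p2-p5 normal with probability 0.25 else
#'   missing (expected pouch score 2); cb2-cb5 normal with probability
#'   0.375 else absent, targeting a mean CB score of 2.5 ("two to three"
#'   ceratobranchials).
#'
#' @param class_name One of `"wild_type"`, `"tbx1"`, `"single_mutant"`,
#'   `"double_mutant"`.
#' @param seed Integer seed stored in the returned params.
#' @return A [phenotype_class_params()] object.
#' @export
phenotype_class <- function(class_name, seed = 1L) {
  cert <- function(state, states) {
    m <- matrix(0, 5, length(states), dimnames = list(NULL, states))
    m[, state] <- 1
    m
  }
  survival_mix <- function(p_survive, states, fail_state) {
    m <- matrix(0, 5, length(states), dimnames = list(NULL, states))
    m[1, "normal"] <- 1
    m[2:5, "normal"] <- p_survive
    m[2:5, fail_state] <- 1 - p_survive
    m
  }
  params <- switch(
    class_name,
    wild_type = list(cert("normal", POUCH_STATES), cert("normal", CB_STATES)),
    tbx1 = list(survival_mix(0, POUCH_STATES, "missing"),
                cert("absent", CB_STATES)),
    single_mutant = list(survival_mix(0.75, POUCH_STATES, "missing"),
                         survival_mix(0.75, CB_STATES, "absent")),
    double_mutant = list(survival_mix(0.25, POUCH_STATES, "missing"),
                         survival_mix(0.375, CB_STATES, "absent")),
    config_error("class_name", sprintf("unknown genotype class '%s'", class_name))
  )
  phenotype_class_params(class_name, params[[1]], params[[2]], seed = seed)
}

#' Simulate phenotype records for one genotype class
#'
#' Draws `n_embryos` independent embryo records (one row per embryo side)
#' from the class state distributions.  After the per-element CB states are
#' drawn, adjacent pairs in which both elements are normal are fused with
#' probability `fusion_prob`, scanning anterior to posterior; a fused pair
#' is recorded in the `fusions` column and its two positions contribute
#' only the fusion score downstream.
#'
#' @param params A [phenotype_class_params()] object (or the result of
#'   [phenotype_class()]).
#' @param n_embryos Number of embryos, >= 1.
#' @param sides Character vector of sides to generate per embryo; default
#'   `"left"` gives one record per embryo, `c("left", "right")` gives two.
#' @param seed Overrides `params$seed` when given.
#' @return A data frame in the phenotype-table dialect: `embryo_id`,
#'   `genotype`, `side`, `p1`..`p5`, `cb1`..`cb5`, `fusions` (fused pairs
#'   encoded like `"2-3;4-5"`, empty string when none).
#' @export
simulate_phenotypes <- function(params, n_embryos, sides = "left",
                                seed = params$seed) {
  if (!inherits(params, "phenotype_class_params")) {
    config_error("params", "must be created by phenotype_class_params()")
  }
  check_scalar_number(n_embryos, "n_embryos", lower = 1)
  if (!all(sides %in% c("left", "right")) || anyDuplicated(sides)) {
    config_error("sides", "must be a subset of c('left', 'right') without duplicates")
  }
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_embryos)) {
      for (s in sides) {
        pouch <- vapply(1:5, function(p) {
          sample(POUCH_STATES, 1L, prob = params$pouch_probs[p, ])
        }, character(1))
        cb <- vapply(1:5, function(p) {
          sample(CB_STATES, 1L, prob = params$cb_probs[p, ])
        }, character(1))
        fusions <- character(0)
        taken <- rep(FALSE, 5)
        for (a in 1:4) {
          if (!taken[a] && !taken[a + 1] &&
              cb[a] == "normal" && cb[a + 1] == "normal" &&
              stats::runif(1) < params$fusion_prob) {
            fusions <- c(fusions, sprintf("%d-%d", a, a + 1))
            taken[c(a, a + 1)] <- TRUE
          }
        }
        row <- data.frame(
          embryo_id = sprintf("%s_e%03d", params$class_name, i),
          genotype = params$class_name, side = s,
          stringsAsFactors = FALSE)
        row[paste0("p", 1:5)] <- as.list(pouch)
        row[paste0("cb", 1:5)] <- as.list(cb)
        row$fusions <- paste(fusions, collapse = ";")
        rows[[length(rows) + 1L]] <- row
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
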