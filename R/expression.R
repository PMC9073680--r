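#' @name expression
#' @title Expression specificity (SPM) and regional enrichment
#' @description The specificity metric (SPM) of a gene for a category
#'   (a life stage, a tissue, or a sex) is the proportion of the gene's
#'   expression found in that category: category means divided by the
#'   sum of category means along the dimension. It ranges over [0, 1]
#'   and sums to 1 across a dimension's categories. A gene is labeled
#'   specific to a category when 70% or more of its expression falls
#'   there, otherwise unbiased. Regional class composition (e.g. inside
#'   an inversion vs the rest of the genome) is compared by Pearson
#'   chi-square.
NULL

.SPM_DIMENSIONS <- c("stage", "tissue", "sex")

# conditions eligible for a dimension: the stage dimension is computed
# on tissues sampled in every stage; the sex dimension only on sexed
# libraries
.dimension_conditions <- function(design, dimension) {
  if (dimension == "stage") {
    tiss <- split(design$tissue, design$stage)
    shared <- Reduce(intersect, tiss)
    design[design$tissue %in% shared, , drop = FALSE]
  } else if (dimension == "sex") {
    design[design$sex %in% c("M", "F"), , drop = FALSE]
  } else {
    design
  }
}

#' Compute SPM profiles along one dimension
#'
#' @param expr gene x condition matrix of non-negative mean expression.
#' @param design condition metadata (`condition`, `stage`, `tissue`,
#'   `sex`); conditions absent from `colnames(expr)` are ignored.
#' @param dimension `"stage"`, `"tissue"`, or `"sex"`.
#' @param threshold labeling threshold (0.70).
#' @param squared use the squared-expression form of the metric instead
#'   of the linear proportion of category means (off by default; the
#'   linear form matches the "proportion of expression" definition and
#'   its 0.90 worked example).
#' @return list with `spm` (gene x category matrix; rows of expressed
#'   genes sum to 1) and `label` (named vector: category or
#'   `"unbiased"`; `NA` for unexpressed genes).
#' @export
compute_spm <- function(expr, design, dimension = c("stage", "tissue", "sex"),
                        threshold = 0.70, squared = FALSE) {
  dimension <- match.arg(dimension)
  .assert(all(expr >= 0, na.rm = TRUE), "expression must be non-negative")
  des <- .dimension_conditions(design, dimension)
  des <- des[des$condition %in% colnames(expr), , drop = FALSE]
  cats <- unique(des[[dimension]])
  .assert(length(cats) >= 2, "dimension needs at least 2 categories")
  means <- sapply(cats, function(cat) {
    cond <- des$condition[des[[dimension]] == cat]
    rowMeans(expr[, cond, drop = FALSE])
  })
  if (squared) means <- means^2
  tot <- rowSums(means)
  spm <- means / tot
  spm[tot == 0, ] <- NA_real_
  label <- rep(NA_character_, nrow(expr))
  names(label) <- rownames(expr)
  expressed <- tot > 0
  top <- max.col(replace(spm, is.na(spm), -1))
  label[expressed] <- ifelse(spm[cbind(seq_len(nrow(spm)), top)][expressed] >= threshold,
                             cats[top[expressed]], "unbiased")
  list(spm = spm, label = label, dimension = dimension, categories = cats)
}

#' Chi-square test of regional class composition
#'
#' Pearson chi-square of the 2 x k (region x class) contingency table
#' against independence; df = k - 1 (sex: male/female/unbiased gives
#' df 2; stages 4 classes df 3; tissues 8 classes df 7). Classes with
#' zero expected count are collapsed into the largest remaining class
#' with a warning.
#'
#' @param inside,outside named integer class counts (aligned names).
#' @return list with `statistic`, `df`, `p_value`, and the `table` used.
#' @export
enrichment_test <- function(inside, outside) {
  .assert(identical(sort(names(inside)), sort(names(outside))),
          "class names must align between the two count vectors")
  outside <- outside[names(inside)]
  tab <- rbind(inside = inside, outside = outside)
  keep <- colSums(tab) > 0
  if (!all(keep)) {
    warning("classes with zero total count collapsed out of the table")
    tab <- tab[, keep, drop = FALSE]
  }
  .assert(ncol(tab) >= 2, "need at least two classes with counts")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab)
}

#' Class counts for genes inside vs outside genomic regions
#'
#' @param labels named specificity labels (from [compute_spm()]).
#' @param genes gene table with `gene_id`, `scaffold`, `start`, `end`.
#' @param regions data.frame with `scaffold`, `start`, `end` (0-based
#'   half-open).
#' @return list of `inside` and `outside` count vectors over the label
#'   classes present.
#' @export
region_class_counts <- function(labels, genes, regions) {
  labs <- labels[!is.na(labels)]
  g <- genes[match(names(labs), genes$gene_id), ]
  inside <- rep(FALSE, length(labs))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    inside <- inside | (g$scaffold == r$scaffold & g$start >= r$start + 1 &
                          g$end <= r$end)
  }
  classes <- sort(unique(labs))
  list(inside = table(factor(labs[inside], levels = classes)),
       outside = table(factor(labs[!inside], levels = classes)))
}
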