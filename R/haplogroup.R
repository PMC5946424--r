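#' Score one sample against a diagnostic-site panel
#'
#' For each haplogroup label, `n_callable` counts panel sites where the
#' sample has a usable (non-missing, non-heterozygous) call and the panel's
#' derived allele matches one of the site's alleles; `n_derived` counts
#' those calls carrying the derived allele.
#'
#' @param gm a [genotype_matrix()] (uncallable calls already set to missing,
#'   e.g. via [mark_uncallable()] for ancient samples).
#' @param sample sample ID to score.
#' @param panel a [extract_panel()] data.frame (`haplogroup`, `pos`,
#'   `ancestral`, `derived`).
#' @return data.frame with `haplogroup`, `n_derived`, `n_callable` (one row
#'   per panel label, including zero rows).
#' @export
score_sample <- function(gm, sample, panel) {
  if (nrow(panel) == 0) stop("panel must be non-empty")
  if (!sample %in% gm_samples(gm)) stop("unknown sample: ", sample)
  idx <- match(panel$pos, gm$pos)
  present <- !is.na(idx)
  derived_code <- rep(NA_integer_, nrow(panel))
  derived_code[present] <- ifelse(
    panel$derived[present] == gm$alt[idx[present]], 1L,
    ifelse(panel$derived[present] == gm$ref[idx[present]], 0L, NA_integer_))
  g <- rep(NA_integer_, nrow(panel))
  g[present] <- gm$geno[sample, idx[present]]
  callable <- !is.na(derived_code) & !is.na(g) & g %in% c(0L, 1L)
  derived <- callable & g == derived_code
  labs <- unique(panel$haplogroup)
  data.frame(
    haplogroup = labs,
    n_derived = vapply(labs, function(l)
      sum(derived[panel$haplogroup == l]), integer(1)),
    n_callable = vapply(labs, function(l)
      sum(callable[panel$haplogroup == l]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

hier_depth <- function(label, hierarchy) {
  d <- 0L
  if (is.null(hierarchy)) return(d)
  p <- unname(hierarchy[label])[1]
  while (!is.na(p)) {
    d <- d + 1L
    p <- unname(hierarchy[p])[1]
  }
  d
}

#' Call a haplogroup from per-label scores
#'
#' Among labels with at least `min_callable` callable diagnostic sites and
#' derived-allele support of at least `min_support`, the most specific label
#' (deepest in the hierarchy) is called; when children are uncallable the
#' ancestral label is retained. Ties between equally specific fully
#' supported labels, or no qualifying label, give a no-call with the full
#' score table retained. Labels with partial support below the threshold
#' are reported as consistent-with annotations (e.g. "2 of 4 callable
#' derived alleles"), not as assignments.
#'
#' @param scores output of [score_sample()].
#' @param hierarchy named character vector (child label -> parent label,
#'   `NA` for roots), e.g. `attr(panel, "hierarchy")`.
#' @param min_callable minimum callable sites for a label to qualify.
#' @param min_support minimum `n_derived/n_callable`; default 1 (all
#'   callable diagnostic sites derived).
#' @param sample optional sample ID carried through to the result.
#' @return list of class `haplogroup_call`: `sample`, `label` (or `NA`),
#'   `n_derived`, `n_callable`, `support`, `scores`, `annotations`.
#' @export
call_haplogroup <- function(scores, hierarchy = NULL, min_callable = 1,
                            min_support = 1.0, sample = NA_character_) {
  support <- ifelse(scores$n_callable > 0,
                    scores$n_derived / scores$n_callable, NA_real_)
  qual <- scores$n_callable >= min_callable & !is.na(support) &
    support >= min_support
  depth <- vapply(scores$haplogroup, hier_depth, integer(1),
                  hierarchy = hierarchy)
  label <- NA_character_
  annotations <- character(0)
  if (any(qual)) {
    dmax <- max(depth[qual])
    cand <- scores$haplogroup[qual & depth == dmax]
    if (length(cand) == 1L) label <- cand
    else annotations <- c(annotations,
                          paste0("tie:", paste(sort(cand), collapse = "|")))
  }
  partial <- !qual & scores$n_derived > 0
  if (any(partial))
    annotations <- c(annotations, sprintf(
      "consistent-with %s (%d/%d)", scores$haplogroup[partial],
      scores$n_derived[partial], scores$n_callable[partial]))
  i <- match(label, scores$haplogroup)
  structure(list(sample = sample, label = label,
                 n_derived = if (is.na(label)) NA_integer_ else
                   scores$n_derived[i],
                 n_callable = if (is.na(label)) NA_integer_ else
                   scores$n_callable[i],
                 support = if (is.na(label)) NA_real_ else support[i],
                 scores = cbind(scores, support = support),
                 annotations = annotations),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  lab <- if (is.na(x$label)) "no-call" else
    sprintf("%s (%d of %d callable derived alleles)", x$label,
            x$n_derived, x$n_callable)
  cat(sprintf("<haplogroup_call> %s: %s\n", x$sample, lab))
  for (a in x$annotations) cat("  ", a, "\n", sep = "")
  invisible(x)
}

#' Call haplogroups for a cohort
#'
#' @param gm a [genotype_matrix()].
#' @param panel a diagnostic panel from [extract_panel()] (or a compatible
#'   data.frame).
#' @param hierarchy label hierarchy; defaults to the panel attribute.
#' @param exclude sample IDs to skip (e.g. the outgroup).
#' @param min_callable,min_support as in [call_haplogroup()].
#' @return list with `calls` (one data.frame row per sample: `sample`,
#'   `label`, `n_derived`, `n_callable`, `support`, `annotations`) and
#'   `frequency` (table of called labels; sums to the number of assigned
#'   samples).
#' @export
assign_cohort <- function(gm, panel, hierarchy = attr(panel, "hierarchy"),
                          exclude = NULL, min_callable = 1,
                          min_support = 1.0) {
  samples <- setdiff(gm_samples(gm), exclude)
  if (length(samples) == 0) stop("sample set must be non-empty")
  calls <- lapply(samples, function(s)
    call_haplogroup(score_sample(gm, s, panel), hierarchy,
                    min_callable, min_support, sample = s))
  df <- data.frame(
    sample = samples,
    label = vapply(calls, `[[`, character(1), "label"),
    n_derived = vapply(calls, function(x) as.integer(x$n_derived),
                       integer(1)),
    n_callable = vapply(calls, function(x) as.integer(x$n_callable),
                        integer(1)),
    support = vapply(calls, function(x) as.numeric(x$support), numeric(1)),
    annotations = vapply(calls, function(x)
      paste(x$annotations, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  list(calls = df, frequency = table(df$label[!is.na(df$label)]),
       details = calls)
}
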