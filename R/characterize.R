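#' Network-overlap percentages
#'
#' Percentage of the map's voxels falling inside each labelled network of a
#' reference atlas; voxels on the atlas background (label 0) are reported
#' as `unassigned`. When the map and atlas grids differ, map voxel centres
#' are assigned by nearest-neighbour lookup in the atlas (labels are
#' categorical).
#'
#' @param map binary/thresholded 3-D [brain_vol] (nonzero = in map).
#' @param atlas integer-labelled 3-D [brain_vol]; 0 = background.
#' @param labels optional named vector mapping label -> network name.
#' @return data.frame with `network`, `label`, `percent`; percentages sum
#'   to 100 including the unassigned row.
#' @export
network_overlap <- function(map, atlas, labels = NULL) {
  stopifnot(inherits(map, "brain_vol"), inherits(atlas, "brain_vol"))
  lin <- which(map$data != 0)
  if (!length(lin)) stop("empty map")
  ijk <- arrayInd(lin, dim(map$data)) - 1L
  if (isTRUE(all.equal(map$affine, atlas$affine)) &&
      identical(dim(map$data), dim(atlas$data))) {
    vox <- ijk
  } else {
    vox <- round(mm_to_voxel(atlas$affine, voxel_to_mm(map$affine, ijk)))
  }
  d <- dim(atlas$data)
  inside <- vox[, 1] >= 0 & vox[, 1] < d[1] &
    vox[, 2] >= 0 & vox[, 2] < d[2] & vox[, 3] >= 0 & vox[, 3] < d[3]
  lab <- rep(0L, nrow(vox))
  if (any(inside)) {
    alin <- vox[inside, , drop = FALSE] %*% c(1, d[1], d[1] * d[2]) + 1
    lab[inside] <- as.integer(atlas$data[as.integer(alin)])
  }
  all_labels <- sort(unique(c(0L, as.integer(atlas$data))))
  counts <- table(factor(lab, levels = all_labels))
  pct <- 100 * as.numeric(counts) / length(lab)
  name <- as.character(all_labels)
  if (!is.null(labels)) {
    hit <- match(name, names(labels))
    name[!is.na(hit)] <- labels[hit[!is.na(hit)]]
  }
  name[all_labels == 0L] <- "unassigned"
  data.frame(network = name, label = all_labels, percent = pct,
             stringsAsFactors = FALSE)
}

#' Conjunction of two thresholded maps
#'
#' Minimum-statistic conjunction over already-thresholded inputs: the
#' voxelwise intersection of the two significant maps.
#'
#' @param map_a,map_b thresholded maps (vectors or [brain_vol]s on the same
#'   grid); nonzero = significant.
#' @return logical vector (or [brain_vol] when volumes were given) of
#'   voxels significant in both maps.
#' @export
conjunction <- function(map_a, map_b) {
  vol_out <- inherits(map_a, "brain_vol")
  a <- if (vol_out) map_a$data else map_a
  b <- if (inherits(map_b, "brain_vol")) map_b$data else map_b
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("grid mismatch between the two maps")
  res <- (a != 0) & (b != 0)
  if (vol_out) brain_vol(array(as.numeric(res), dim(a)), map_a$affine) else res
}

# studies activating the seed: >= 1 focus inside the seed mask (consistent
# with the cbma selection rule)
.activates <- function(db, seed) {
  ids <- suppressWarnings(select_studies_in_mask(db, seed))
  as.character(db$studies$study_id) %in% ids
}

# vectorized 2x2 chi-square over terms; a,b,c,d columns
.chisq_2x2 <- function(a, b, c_, d, correct = FALSE) {
  n <- a + b + c_ + d
  num <- a * d - b * c_
  if (correct) num <- pmax(abs(num) - n / 2, 0) * sign(num)
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- ifelse(den == 0, 0, n * num^2 / den)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(stat = stat, p = p)
}

#' Forward-inference (consistency) functional decoding
#'
#' BrainMap-style chi-square decoding: for every term, studies are
#' cross-classified by seed activation (>= 1 focus inside the seed) and
#' term presence (frequency above `presence_threshold`). The forward
#' statistic is the likelihood `P(activation | term)`, compared against the
#' base rate `P(activation)`, with an independence chi-square test on the
#' 2x2 table.
#'
#' @param db a `coordinate_db` with a term matrix.
#' @param seed binary 3-D [brain_vol] seed mask.
#' @param presence_threshold a term is "present" in a study when its
#'   frequency exceeds this value (default 0: any positive frequency).
#' @param correct apply the Yates continuity correction.
#' @return data.frame (one row per term present in >= 1 study): counts
#'   `a` (activating, term), `b` (non-activating, term), `c` (activating,
#'   no term), `d` (neither), `chisq`, `p`, `direction` (+1 when the term
#'   is enriched among activating studies), `likelihood`
#'   (`P(activation | term)`), `base_rate` (`P(activation)`).
#' @export
decode_forward <- function(db, seed, presence_threshold = 0, correct = FALSE) {
  if (is.null(db$terms)) stop("database has no term matrix")
  act <- .activates(db, seed)
  if (!any(act)) stop("no study activates the seed")
  pres <- db$terms > presence_threshold
  dropped <- colSums(pres) == 0
  pres <- pres[, !dropped, drop = FALSE]
  if (any(dropped))
    message(sum(dropped), " term(s) present in no study excluded")
  a <- colSums(pres[act, , drop = FALSE])
  b <- colSums(pres[!act, , drop = FALSE])
  c_ <- sum(act) - a
  d <- sum(!act) - b
  cs <- .chisq_2x2(a, b, c_, d, correct)
  data.frame(term = colnames(pres), a = a, b = b, c = c_, d = d,
             chisq = cs$stat, p = cs$p,
             direction = sign(a / pmax(a + b, 1) - (a + c_) / length(act)),
             likelihood = a / (a + b),
             base_rate = sum(act) / length(act),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Reverse-inference (specificity) functional decoding
#'
#' Posterior probability of a study containing the term given activation
#' inside the seed, `P(term | activation)`, via Bayes' rule. With the
#' empirical term base rate as prior this is `a / (a + c)`; a uniform
#' (0.5) prior variant is selectable. The chi-square column tests the same
#' 2x2 table as the forward analysis.
#'
#' @inheritParams decode_forward
#' @param prior `"empirical"` or `"uniform"`.
#' @return data.frame per term: counts, `chisq`, `p`, `direction`,
#'   `posterior` (`P(term | activation)`), `prior_prob`.
#' @export
decode_reverse <- function(db, seed, presence_threshold = 0, correct = FALSE,
                           prior = c("empirical", "uniform")) {
  prior <- match.arg(prior)
  tab <- decode_forward(db, seed, presence_threshold, correct)
  with(tab, {
    p_act_term <- a / pmax(a + b, 1)
    p_act_noterm <- c / pmax(c + d, 1)
    pr <- if (prior == "empirical") (a + b) / (a + b + c + d) else 0.5
    num <- p_act_term * pr
    den <- num + p_act_noterm * (1 - pr)
    posterior <- ifelse(den == 0, 0, num / den)
    data.frame(term = term, a = a, b = b, c = c, d = d, chisq = chisq, p = p,
               direction = direction, posterior = posterior, prior_prob = pr,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment; rejected hypotheses are those with adjusted
#' value at most `q`. Adjusted values are monotone nondecreasing in the raw
#' p-values.
#'
#' @param p_values raw p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `q_values` (BH-adjusted) and `reject` (logical).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p_values, method = "BH")
  list(q_values = qv, reject = !is.na(qv) & qv <= q)
}

#' Filter decoding terms by cognitive-likelihood annotation
#'
#' Keeps terms whose annotated likelihood of being related to cognitive
#' function is at least `min_likelihood` (boundary inclusive); terms
#' without an annotation are dropped and counted in a message.
#'
#' @param table decoding data.frame with a `term` column.
#' @param annotation data.frame with columns `term` and `likelihood`.
#' @param min_likelihood retention threshold, default 0.8.
#' @return the filtered table.
#' @export
filter_cognitive_terms <- function(table, annotation, min_likelihood = 0.8) {
  if (!nrow(annotation)) {
    warning("empty annotation map: no terms retained")
    return(table[0, , drop = FALSE])
  }
  lik <- annotation$likelihood[match(table$term, annotation$term)]
  unannotated <- is.na(lik)
  if (any(unannotated))
    message(sum(unannotated), " unannotated term(s) dropped")
  table[!unannotated & lik >= min_likelihood, , drop = FALSE]
}

#' Full decoding of a seed: forward + reverse with FDR and term filter
#'
#' @inheritParams decode_forward
#' @param annotation optional cognitive-likelihood annotation table.
#' @param q FDR level, default 0.05.
#' @param min_likelihood cognitive-term filter threshold.
#' @return list of data.frames `forward` and `reverse`, each with
#'   `q_value` and `significant` columns, filtered to annotated cognitive
#'   terms when an annotation is given. FDR is applied per analysis
#'   (direction) separately.
#' @export
decode_seed <- function(db, seed, annotation = NULL, q = 0.05,
                        presence_threshold = 0, min_likelihood = 0.8,
                        correct = FALSE) {
  fwd <- decode_forward(db, seed, presence_threshold, correct)
  rev <- decode_reverse(db, seed, presence_threshold, correct)
  add_fdr <- function(tab) {
    f <- bh_fdr(tab$p, q)
    tab$q_value <- f$q_values
    tab$significant <- f$reject
    tab
  }
  fwd <- add_fdr(fwd)
  rev <- add_fdr(rev)
  if (!is.null(annotation)) {
    fwd <- filter_cognitive_terms(fwd, annotation, min_likelihood)
    rev <- filter_cognitive_terms(rev, annotation, min_likelihood)
  }
  list(forward = fwd, reverse = rev)
}
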