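atlas_fixture <- function() {
  arr <- array(0L, c(6, 6, 2))
  arr[1:3, , ] <- 1L; arr[4:5, , ] <- 3L    # label 2 unused on purpose
  brain_vol(arr, diag(c(2, 2, 2, 1)))
}

test_that("network overlap partitions the map into labelled percentages", {
  atlas <- atlas_fixture()
  inside3 <- array(0, c(6, 6, 2)); inside3[4:5, 1:3, 1] <- 1
  ov <- network_overlap(brain_vol(inside3, atlas$affine), atlas,
                        labels = c("1" = "visual", "3" = "control"))
  expect_equal(ov$percent[ov$network == "control"], 100)
  expect_equal(sum(ov$percent), 100)

  half <- array(0, c(6, 6, 2)); half[3, 1:2, 1] <- 1; half[6, 1:2, 1] <- 1
  ov2 <- network_overlap(brain_vol(half, atlas$affine), atlas)
  expect_equal(ov2$percent[ov2$label == 1], 50)
  expect_equal(ov2$percent[ov2$network == "unassigned"], 50)
  expect_equal(sum(ov2$percent), 100)
  expect_error(network_overlap(brain_vol(array(0, c(6, 6, 2)), atlas$affine),
                               atlas), "empty")
})

test_that("network overlap follows atlas labels under relabeling", {
  atlas <- atlas_fixture()
  m <- array(0, c(6, 6, 2)); m[1:5, 1, 1] <- 1
  ov <- network_overlap(brain_vol(m, atlas$affine), atlas)
  swapped <- atlas
  swapped$data[swapped$data == 1L] <- 99L
  ov2 <- network_overlap(brain_vol(m, atlas$affine), swapped)
  expect_equal(ov$percent[ov$label == 1], ov2$percent[ov2$label == 99])
})

test_that("conjunction is the commutative intersection of thresholded maps", {
  a <- c(1.2, 0, 3, 0)
  b <- c(0.5, 0, 0, 2)
  expect_equal(conjunction(a, b), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(conjunction(a, b), conjunction(b, a))
  expect_equal(conjunction(a, c(0, 0, 0, 0)), rep(FALSE, 4))  # disjoint
  sub <- c(1.2, 0, 0, 0)
  expect_equal(conjunction(a, sub), sub != 0)                  # A subset of B
  expect_error(conjunction(a, b[1:3]), "mismatch")
})

test_that("2x2 chi-square decoding matches the brute-force oracle", {
  # toy table a=30 b=10 c=10 d=50 built as an explicit study set
  n <- 100
  act <- rep(c(TRUE, FALSE), c(40, 60))
  term <- c(rep(c(1, 0), c(30, 10)), rep(c(1, 0), c(10, 50)))
  studies <- data.frame(study_id = sprintf("s%03d", 1:n), n_subjects = 20)
  # activating studies place a focus at the seed voxel centre
  foci <- data.frame(study_id = studies$study_id,
                     x = ifelse(act, 1, 50), y = 1, z = 1)
  terms <- matrix(term, ncol = 1, dimnames = list(studies$study_id, "alpha"))
  db <- coordinate_db(studies, foci, terms)
  seed <- brain_vol(array(c(1, rep(0, 7)), c(2, 2, 2)),
                    { a <- diag(c(2, 2, 2, 1)); a[1:3, 4] <- c(0, 0, 0); a })
  fwd <- decode_forward(db, seed)
  expect_equal(c(fwd$a, fwd$b, fwd$c, fwd$d), c(30, 10, 10, 50))

  # brute-force chi-square from expected counts
  obs <- matrix(c(30, 10, 10, 50), 2, byrow = TRUE)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi_brute <- sum((obs - expected)^2 / expected)
  expect_equal(fwd$chisq, chi_brute, tolerance = 1e-12)
  # independent cross-check against the standard implementation
  expect_equal(fwd$chisq,
               unname(chisq.test(obs, correct = FALSE)$statistic),
               tolerance = 1e-10)
  expect_equal(fwd$p,
               unname(chisq.test(obs, correct = FALSE)$p.value),
               tolerance = 1e-10)

  expect_equal(fwd$likelihood, 30 / 40)     # P(activation | term) = 0.75
  expect_equal(fwd$base_rate, 0.4)
  expect_equal(fwd$direction, 1)

  rev <- decode_reverse(db, seed)
  expect_equal(rev$posterior, 30 / 40)      # P(term | activation) = 0.75

  # continuity-corrected variant agrees with chisq.test(correct = TRUE)
  fwd_cc <- decode_forward(db, seed, correct = TRUE)
  expect_equal(fwd_cc$chisq,
               unname(chisq.test(obs, correct = TRUE)$statistic),
               tolerance = 1e-10)
})

test_that("decoding boundary cases and duplication invariance hold", {
  studies <- data.frame(study_id = sprintf("s%02d", 1:20), n_subjects = 15)
  act <- rep(c(TRUE, FALSE), each = 10)
  foci <- data.frame(study_id = studies$study_id,
                     x = ifelse(act, 1, 50), y = 1, z = 1)
  seed <- brain_vol(array(c(1, rep(0, 7)), c(2, 2, 2)), diag(c(2, 2, 2, 1)))

  # term present in every activating study and no others -> posterior 1
  terms <- matrix(as.numeric(act), ncol = 1,
                  dimnames = list(studies$study_id, "pure"))
  db <- coordinate_db(studies, foci, terms)
  expect_equal(decode_reverse(db, seed)$posterior, 1)

  # term distributed identically across groups -> chi-square exactly 0
  terms2 <- matrix(rep(c(1, 0), 10), ncol = 1,
                   dimnames = list(studies$study_id, "flat"))
  db2 <- coordinate_db(studies, foci, terms2)
  expect_equal(decode_forward(db2, seed)$chisq, 0, tolerance = 1e-12)

  # duplicating every study leaves the empirical-prior posterior unchanged
  dup_ids <- c(studies$study_id, paste0(studies$study_id, "b"))
  studies_d <- data.frame(study_id = dup_ids, n_subjects = 15)
  foci_d <- rbind(foci, transform(foci, study_id = paste0(study_id, "b")))
  terms_d <- matrix(rep(terms[, 1], 2), ncol = 1,
                    dimnames = list(dup_ids, "pure"))
  db_d <- coordinate_db(studies_d, foci_d, terms_d)
  expect_equal(decode_reverse(db_d, seed)$posterior,
               decode_reverse(db, seed)$posterior, tolerance = 1e-12)
})

test_that("BH step-up matches a brute-force walk over sorted p-values", {
  out <- bh_fdr(0.04, q = 0.05)
  expect_true(out$reject)

  p <- c(0.01, 0.02, 0.03, 0.9)
  res <- bh_fdr(p, q = 0.05)
  # brute force: largest k with p_(k) <= k q / m
  m <- length(p); sp <- sort(p)
  kmax <- max(c(0, which(sp <= seq_len(m) * 0.05 / m)))
  expect_equal(sum(res$reject), kmax)
  expect_true(all(res$reject[1:3]) && !res$reject[4])
  # adjusted values monotone in raw p
  ord <- order(p)
  expect_true(all(diff(res$q_values[ord]) >= -1e-12))
  # agreement with p.adjust is definitional; check the brute-force adjusted
  # values instead: q_i = min over j >= i of m p_(j) / j
  qs <- sapply(seq_len(m), function(i) min(m * sp[i:m] / (i:m)))
  expect_equal(sort(res$q_values), qs, tolerance = 1e-12)

  expect_false(any(bh_fdr(rep(1, 5), 0.05)$reject))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("cognitive-term filter applies the inclusive 80% boundary", {
  tab <- data.frame(term = c("t1", "t2", "t3", "t4"), chisq = 1:4)
  ann <- data.frame(term = c("t1", "t2", "t3"),
                    likelihood = c(0.8, 0.79, 0.95))
  expect_message(out <- filter_cognitive_terms(tab, ann), "unannotated")
  expect_equal(out$term, c("t1", "t3"))    # 0.8 kept, 0.79 dropped, t4 unannotated
  expect_warning(empty <- filter_cognitive_terms(tab, ann[0, ]), "empty")
  expect_equal(nrow(empty), 0)
  mixed <- filter_cognitive_terms(tab[1:3, ], ann)
  expect_equal(nrow(mixed), sum(ann$likelihood >= 0.8))
})

test_that("planted term-network coupling is recovered by decoding", {
  # recovery of the full planted term set is a consistency property: the
  # chi-square separation grows with corpus size and coupling strength, so
  # it is evaluated in a strongly coupled corpus (300 studies, rate
  # elevation 9x) where near-certain recovery is expected
  hits <- 0
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    cfg <- tiny_config(dims = c(10L, 10L, 2L), n_studies = 300L,
                       association_strength = 8, seed = 500L + s)
    out <- simulate_coordinate_db(cfg)
    roi <- make_roi(cfg$dims)
    w <- out$truth$w1
    hi <- order(w, decreasing = TRUE)[1:40]   # the 20% high-weight tail
    seed_vol <- roi_to_volume(as.numeric(seq_len(roi$n_voxels) %in% hi), roi)
    fwd <- decode_forward(out$db, seed_vol)
    planted <- names(which(out$truth$term_affiliation == "A"))
    top <- fwd$term[order(fwd$chisq * fwd$direction, decreasing = TRUE)][
      seq_along(planted)]
    if (all(planted %in% top)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
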