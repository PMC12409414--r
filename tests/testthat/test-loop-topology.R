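mk_set <- function(rows, label) {
  dt <- rbindlist(lapply(rows, function(r) {
    data.table(chrom = r$chrom %||% "chr1", start1 = r$a[1], end1 = r$a[2],
               start2 = r$b[1], end2 = r$b[2], resolution_bp = 1000L,
               score = NA_real_, cell_label = label)
  }))
  dt[, loop_id := sprintf("%s%d", label, seq_len(.N))]
  loopvar:::as_loop_set(dt, label)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("match_loops classifies constructed shared / one-anchor / unique loops", {
  A <- mk_set(list(list(a = c(0, 1000), b = c(5000, 6000)),
                   list(a = c(0, 1000), b = c(9000, 10000))), "L")
  B <- mk_set(list(list(a = c(0, 1000), b = c(5000, 6000))), "M")
  res <- match_loops(A, B, slack_bins = 0L)
  expect_equal(res$a$match_class, c("shared_loop", "shared_single_anchor"))
  expect_equal(res$a$matched_loop_id, c("M1", NA))
  expect_equal(res$b$match_class, "shared_loop")

  # identical sets: no unique loops in either direction
  res2 <- match_loops(A, A, slack_bins = 0L)
  expect_true(all(res2$a$match_class == "shared_loop"))
  expect_true(all(res2$b$match_class == "shared_loop"))
})

test_that("match_loops matches anchors orientation-agnostically", {
  # left anchor of A equals right anchor of B and vice versa
  A <- mk_set(list(list(a = c(0, 1000), b = c(9000, 10000))), "L")
  B <- mk_set(list(list(a = c(0, 1000), b = c(9000, 10000)),
                   list(a = c(9000, 10000), b = c(20000, 21000))), "M")
  res <- match_loops(A, B)
  expect_equal(res$a$match_class, "shared_loop")
  expect_equal(res$b$match_class, c("shared_loop", "shared_single_anchor"))
})

test_that("classification matches the all-pairs brute force on random sets", {
  set.seed(42)
  for (rep in 1:20) {
    A <- rand_loop_set(50, "A")
    B <- rand_loop_set(50, "B")
    res <- match_loops(A, B, slack_bins = 0L)
    expect_equal(res$a$match_class, brute_classify(A, B))
    expect_equal(res$b$match_class, brute_classify(B, A))
    # shared counts symmetric; classes partition each set
    expect_equal(sum(res$a$match_class == "shared_loop") > 0,
                 sum(res$b$match_class == "shared_loop") > 0)
    expect_equal(nrow(res$a), 50L)
    expect_equal(nrow(res$b), 50L)
  }
})

test_that("shared_loop count is monotone non-decreasing in slack_bins", {
  set.seed(7)
  for (rep in 1:5) {
    A <- rand_loop_set(40, "A")
    B <- rand_loop_set(40, "B")
    shared <- vapply(c(0L, 1L, 2L, 4L), function(s) {
      sum(match_loops(A, B, s)$a$match_class == "shared_loop")
    }, 0L)
    expect_true(all(diff(shared) >= 0))
  }
})

test_that("matched_loop_id picks the maximal-overlap partner deterministically", {
  A <- mk_set(list(list(a = c(0, 1000), b = c(5000, 6000))), "L")
  # M1 overlaps both anchors partially; M2 matches exactly (larger summed overlap)
  B <- mk_set(list(list(a = c(500, 1500), b = c(5500, 6500)),
                   list(a = c(0, 1000), b = c(5000, 6000))), "M")
  res <- match_loops(A, B)
  expect_equal(res$a$matched_loop_id, "M2")
})

test_that("contact_regions reduces anchors to unique sorted intervals", {
  A <- mk_set(list(list(a = c(0, 1000), b = c(5000, 6000)),
                   list(a = c(0, 1000), b = c(9000, 10000))), "L")
  cr <- contact_regions(A)
  expect_equal(nrow(cr), 3L)
  expect_equal(cr$start, c(0L, 5000L, 9000L))
  expect_equal(nrow(contact_regions(rand_loop_set(0, "E"))), 0L)

  set.seed(5)
  B <- rand_loop_set(100, "B")
  expect_equal(nrow(contact_regions(B)),
               nrow(unique(rbind(
                 data.table(c = B$chrom, s = B$start1, e = B$end1),
                 data.table(c = B$chrom, s = B$start2, e = B$end2)))))
  expect_lte(nrow(contact_regions(B)), 2L * nrow(B))
})

test_that("contact_annotation_fraction agrees with all-pairs brute force", {
  contacts <- data.table(chrom = "chr1", start = 0L, end = 1000L)
  ann <- data.table(chrom = "chr1", start = 500L, end = 600L)
  expect_equal(contact_annotation_fraction(contacts, ann), 1.0)
  expect_equal(contact_annotation_fraction(
    contacts, data.table(chrom = "chr1", start = 5000L, end = 6000L)), 0.0)

  set.seed(31)
  for (rep in 1:5) {
    cc <- rand_intervals(200); aa <- rand_intervals(200)
    brute <- mean(vapply(seq_len(nrow(cc)), function(i) {
      any(cc$chrom[i] == aa$chrom & cc$start[i] < aa$end & aa$start < cc$end[i])
    }, TRUE))
    expect_equal(contact_annotation_fraction(cc, aa), brute)
  }
})

test_that("region_loop_count_test doubles the smaller exact binomial tail", {
  expect_equal(region_loop_count_test(22, 7), 2 * pbinom(7, 29, 0.5))
  expect_equal(round(region_loop_count_test(22, 7), 5), 0.00813)
  expect_equal(round(region_loop_count_test(6, 3), 4), 0.5078)
  for (k in c(1, 5, 20)) expect_equal(region_loop_count_test(k, k), 1.0)
  expect_lt(region_loop_count_test(66, 24), 1e-4)
  expect_error(region_loop_count_test(0, 0), "undefined")
  # chi-square alternative is a valid p-value and agrees in direction
  expect_lt(region_loop_count_test(66, 24, method = "chisq"), 1e-4)
})
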