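test_that("rate_classes builds and validates partitions", {
  tr <- fig1()
  cls <- rate_classes(tr, list(c("beta", "gamma")))
  expect_length(cls, 3L)
  expect_identical(names(cls), c("alpha", "beta=gamma", "delta"))
  expect_length(rate_classes(tr), 4L)
  expect_error(rate_classes(tr, list(c("beta", "zz"))), "unknown rate")
  expect_error(rate_classes(tr, list(c("beta", "gamma"), c("gamma", "delta"))),
               "two classes")
})

test_that("merge_basis sums member matrices and keeps supports disjoint", {
  tr <- fig1()
  merged <- merge_basis(tr, rate_classes(tr, list(c("beta", "gamma"))))
  expect_length(merged, 3L)
  expect_true(all(merged[["beta=gamma"]] == fig1_Q$beta + fig1_Q$gamma))

  ## all-singleton classes reproduce the original basis
  expect_identical(merge_basis(tr, rate_classes(tr)), basis(tr))

  km <- merge_basis(k2p(), attr(k2p(), "rate_classes"))
  expect_length(km, 2L)
  expect_identical(dim(km[[1]]), c(4L, 4L))
})

test_that("merged spans are contained in the unique-rate algebra", {
  for (tr in random_tree_batch(20, 4, 8, seed0 = 1500)) {
    rs <- rates(tr)
    if (length(rs) < 2L) next
    cls <- rate_classes(tr, list(rs[1:2]))
    merged <- merge_basis(tr, cls)
    b <- basis(tr)
    for (nm in names(merged)) {
      res <- span_coeffs(merged[[nm]], b)
      expect_true(res$in_span)
      expect_true(all(res$coeffs == 1))
      expect_setequal(names(res$coeffs), cls[[nm]])
    }
  }
})

test_that("classify_pair assigns the five configurations on the example", {
  tr <- fig1()
  v <- function(r) rate_vertex(tr, r)

  c1 <- classify_pair(tr, v("alpha"), v("delta"))
  expect_identical(c1$case, 1L); expect_false(c1$algebra)

  c2 <- classify_pair(tr, v("beta"), v("delta"))
  expect_identical(c2$case, 2L); expect_false(c2$algebra)

  c3 <- classify_pair(tr, v("beta"), v("gamma"))
  expect_identical(c3$case, 3L); expect_false(c3$algebra)

  kt <- k2p()
  c4 <- classify_pair(kt, rate_vertex(kt, "b"), rate_vertex(kt, "c"))
  expect_identical(c4$case, 4L); expect_true(c4$algebra)

  c5 <- classify_pair(tr, v("alpha"), v("beta"))
  expect_identical(c5$case, 5L); expect_true(c5$algebra)

  expect_error(classify_pair(tr, v("alpha"), v("alpha")), "distinct")
  expect_error(classify_pair(tr, v("alpha"), taxon_vertex(tr, "1")),
               "non-leaf")
})

test_that("classification is symmetric in the two vertices", {
  for (tr in random_tree_batch(15, 4, 7, seed0 = 1600)) {
    iv <- internal_vertices(tr)
    if (length(iv) < 2L) next
    for (i in seq_along(iv)) {
      for (j in seq_len(i - 1L)) {
        expect_identical(classify_pair(tr, iv[i], iv[j])$case,
                         classify_pair(tr, iv[j], iv[i])$case)
      }
    }
  }
})

test_that("connected_identification_check detects parent-child chains", {
  tr <- fig1()
  expect_true(connected_identification_check(
    tr, rate_classes(tr, list(c("alpha", "gamma")))))
  expect_true(connected_identification_check(
    tr, rate_classes(tr, list(c("alpha", "beta", "gamma")))))
  expect_false(connected_identification_check(
    tr, rate_classes(tr, list(c("beta", "delta")))))
  expect_false(connected_identification_check(
    tr, rate_classes(tr, list(c("beta", "gamma")))))
  expect_true(connected_identification_check(tr, rate_classes(tr)))
})

test_that("decide_algebra agrees with the characterisation on the example", {
  tr <- fig1()
  d1 <- decide_algebra(tr, rate_classes(tr, list(c("beta", "gamma"))))
  expect_false(d1$closed)
  expect_identical(d1$case, 3L)

  d2 <- decide_algebra(tr, rate_classes(tr, list(c("beta", "delta"))))
  expect_false(d2$closed)
  expect_identical(d2$case, 2L)

  d3 <- decide_algebra(tr, rate_classes(tr, list(c("alpha", "beta"))))
  expect_true(d3$closed)
  expect_identical(d3$case, 5L)

  kt <- k2p()
  dk <- decide_algebra(kt, attr(kt, "rate_classes"))
  expect_true(dk$closed)
  expect_identical(dk$case, 4L)

  du <- decide_algebra(tr, rate_classes(tr))
  expect_true(du$closed)
  expect_match(du$rationale, "unique rates")

  ## connected multi-rate identification: sufficient condition fires
  dc <- decide_algebra(tr, rate_classes(tr, list(c("alpha", "beta", "gamma"))))
  expect_true(dc$closed)
  expect_match(dc$rationale, "connected")
})

test_that("five-case verdicts equal the generic closure check exhaustively", {
  ## machine check of the single-pair characterisation at small scale
  for (tr in random_tree_batch(40, 3, 7, seed0 = 1700)) {
    iv <- internal_vertices(tr)
    rs <- rates(tr)
    if (length(iv) < 2L) next
    for (i in seq_along(iv)) {
      for (j in seq_len(i - 1L)) {
        verdict <- classify_pair(tr, iv[i], iv[j])$algebra
        merged <- merge_basis(tr, rate_classes(tr, list(rs[c(i, j)])))
        expect_identical(verdict, closure_check(merged)$closed,
                         label = paste(write_newick(tr), rs[i], rs[j]))
      }
    }
  }
})

test_that("the K2P model is a closed two-parameter algebra", {
  kt <- k2p()
  cls <- attr(kt, "rate_classes")
  expect_identical(parameter_count(kt, cls), 2L)
  merged <- merge_basis(kt, cls)
  expect_true(closure_check(merged)$closed)

  pat <- export_symbolic(kt, cls)
  transitions <- c(pat["A", "G"], pat["G", "A"], pat["C", "T"], pat["T", "C"])
  expect_length(unique(transitions), 1L)
  others <- pat[row(pat) != col(pat)]
  transversions <- setdiff(others, transitions)
  expect_length(unique(transversions), 1L)
  expect_false(unique(transversions) %in% transitions)
})

test_that("parameter_count counts equality classes", {
  tr <- fig1()
  expect_identical(parameter_count(tr), 4L)
  expect_identical(parameter_count(tr, rate_classes(tr, list(c("beta", "gamma")))),
                   3L)
  big <- random_tree(20, seed = 3)   # binary: n - 1 internal vertices
  expect_identical(parameter_count(big), 19L)
})

test_that("export_symbolic renders the generic element patterns", {
  tr <- fig1()
  pat <- export_symbolic(tr)
  expect_identical(pat["1", "2"], "beta")
  expect_identical(pat["2", "1"], "beta")
  expect_true(all(pat[c("1", "2"), c("3", "4", "5")] == "alpha"))
  expect_identical(pat["3", "4"], "gamma")
  expect_identical(pat["4", "5"], "delta")
  expect_true(all(diag(pat) == "*"))

  star <- tree_from_hierarchy(hierarchy(letters[1:4]))
  ps <- export_symbolic(star)
  expect_length(unique(ps[row(ps) != col(ps)]), 1L)

  lines <- format_symbolic(pat)
  expect_length(lines, 6L)
})
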