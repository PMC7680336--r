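test_that("square_entrywise matches frozen squares and the brute force", {
  tr <- fig1()
  sq_gamma <- square_entrywise(tr, "gamma")
  frozen <- matrix(0, 5, 5, dimnames = list(as.character(1:5),
                                            as.character(1:5)))
  frozen[3:5, 3:5] <- matrix(c(6, -3, -3,
                               -3, 2, 1,
                               -3, 1, 2), 3, 3, byrow = TRUE)
  expect_identical(unname(sq_gamma + 0), unname(frozen))
  expect_true(all(sq_gamma == fig1_Q$gamma %*% fig1_Q$gamma))

  sq_delta <- square_entrywise(tr, "delta")
  expect_identical(unname(diag(sq_delta) + 0), c(0, 0, 0, 2, 2))
  expect_identical(sq_delta["4", "5"] + 0, -2)
  expect_true(all(sq_delta == fig1_Q$delta %*% fig1_Q$delta))

  cherry <- parse_newick("(a,b)r;")
  expect_identical(unname(square_entrywise(cherry, "r") + 0),
                   matrix(c(2, -2, -2, 2), 2, 2))

  for (tr in random_tree_batch(40, 3, 10, seed0 = 1100)) {
    b <- basis(tr)
    for (r in rates(tr)) {
      expect_true(all(square_entrywise(tr, r) == b[[r]] %*% b[[r]]))
    }
  }
})

test_that("closed-form product expansions match the worked example", {
  tr <- fig1()
  expect_identical(product_coeffs(tr, "alpha", "gamma"), c(gamma = -2))
  expect_identical(product_coeffs(tr, "gamma", "alpha"), c(gamma = -2))
  expect_length(product_coeffs(tr, "beta", "delta"), 0L)
  expect_identical(product_coeffs(tr, "gamma", "gamma"),
                   c(gamma = -3, delta = 1))
  expect_error(product_coeffs(tr, "alpha", "zz"), "unknown rate")
})

test_that("every expansion reconstructs the brute-force product exactly", {
  for (tr in random_tree_batch(50, 3, 12, seed0 = 1200)) {
    b <- basis(tr)
    rs <- rates(tr)
    for (i in seq_along(rs)) {
      for (j in i:length(rs)) {
        cf <- product_coeffs(tr, rs[i], rs[j])
        prod <- b[[rs[i]]] %*% b[[rs[j]]]
        expect_true(all(coeffs_to_matrix(cf, b) == prod),
                    label = paste(write_newick(tr), rs[i], rs[j]))
        ## commutativity (products of symmetric matrices in the algebra)
        expect_true(all(prod == b[[rs[j]]] %*% b[[rs[i]]]))
      }
    }
  }
})

test_that("structure constants are complete, symmetric and validated", {
  sc <- structure_constants(fig1())
  expect_length(sc$entries, 10L)
  expect_length(sc$entries[["beta*delta"]], 0L)
  expect_identical(sc$entries[["alpha*gamma"]], c(gamma = -2))

  cherry <- structure_constants(parse_newick("(a,b)r;"))
  expect_identical(cherry$entries[["r*r"]], c(r = -2))
})

test_that("span_coeffs reads coefficients off disjoint supports, exactly", {
  tr <- fig1()
  b <- basis(tr)
  res <- span_coeffs(j_matrix(5, taxa(tr)), b)
  expect_true(res$in_span)
  expect_identical(res$coeffs,
                   c(alpha = 1, beta = 1, gamma = 1, delta = 1))

  zero <- span_coeffs(b$alpha * 0, b)
  expect_true(zero$in_span)
  expect_length(zero$coeffs, 0L)

  sq <- span_coeffs(fig1_Q$gamma %*% fig1_Q$gamma, b)
  expect_true(sq$in_span)
  expect_identical(sq$coeffs, c(gamma = -3, delta = 1))

  ## off-span: identity matrix has no support cell and nonzero diagonal
  out <- span_coeffs(diag(5), b)
  expect_false(out$in_span)
  expect_true(all(out$residual == diag(5)))

  ## cross-check against the independent linear-solve oracle
  for (tr in random_tree_batch(10, 3, 8, seed0 = 1300)) {
    b <- basis(tr)
    m <- b[[1]] %*% b[[length(b)]]
    expect_identical(span_coeffs(m, b)$in_span, span_solve_oracle(m, b)$in_span)
  }
})

test_that("closure_check certifies unique-rate bases and flags merged ones", {
  tr <- fig1()
  b <- basis(tr)
  expect_true(closure_check(b)$closed)

  merged <- c(b["alpha"], list("beta=gamma" = b$beta + b$gamma), b["delta"])
  rep <- closure_check(merged)
  expect_false(rep$closed)
  expect_true(!is.null(rep$witness$residual))

  single_j <- list(J = j_matrix(4))
  expect_true(closure_check(single_j)$closed)

  expect_error(closure_check(list(A = matrix(1, 2, 2))), "malformed basis")

  for (tr in random_tree_batch(30, 3, 10, seed0 = 1400)) {
    expect_true(closure_check(basis(tr))$closed)
  }
})

test_that("walk counts explain the adjacency products", {
  tr <- fig1()
  ga <- mrca_graph(tr, "alpha")
  gg <- mrca_graph(tr, "gamma")
  a2 <- adjacency(ga) %*% adjacency(ga)
  ab <- adjacency(ga) %*% adjacency(gg)
  for (i in taxa(tr)) {
    for (j in taxa(tr)) {
      expect_identical(a2[i, j], count_two_walks(ga, ga, i, j))
      expect_identical(ab[i, j], count_two_walks(ga, gg, i, j))
    }
  }
})

test_that("instantiate builds Q and transition_matrix reports det(I+Q)", {
  tr <- fig1()
  b <- basis(tr)
  zero <- instantiate(b, c(alpha = 0, beta = 0, gamma = 0, delta = 0))
  expect_true(all(zero$Q == 0))
  expect_true(zero$proper)
  tm0 <- transition_matrix(zero$Q)
  expect_true(tm0$invertible)
  expect_equal(tm0$det, 1)

  ones <- instantiate(b, c(alpha = 1, beta = 1, gamma = 1, delta = 1))
  expect_true(all(ones$Q == j_matrix(5, taxa(tr))))
  tm1 <- transition_matrix(ones$Q)
  ## J has eigenvalues 0 (once) and -5 (four times), so det(I+J) = (-4)^4
  expect_equal(tm1$det, 256)
  expect_true(tm1$invertible)

  neg <- instantiate(b, c(alpha = -1, beta = 2, gamma = 2, delta = 2))
  expect_false(neg$proper)

  expect_error(instantiate(b, c(alpha = 1)), "missing rate value")
})

test_that("exponentials of closed-span rate matrices stay in I + span", {
  for (seed in c(11, 12, 13)) {
    tr <- random_tree(6, seed = seed, max_children = 3)
    b <- basis(tr)
    set.seed(seed)
    vals <- setNames(sample(-5:5, length(b), replace = TRUE) / 4,
                     names(b))
    q <- instantiate(b, vals)$Q
    for (t in c(0.1, 1)) {
      e <- as.matrix(Matrix::expm(t * q)) - diag(nrow(q))
      dimnames(e) <- dimnames(q)
      ## project on support coefficients; residual must vanish numerically
      cf <- vapply(b, function(bm) {
        cell <- which(bm != 0 & row(bm) != col(bm), arr.ind = TRUE)[1, ]
        e[cell[1], cell[2]]
      }, numeric(1))
      resid <- e - coeffs_to_matrix(cf, b)
      expect_lt(max(abs(resid)), 1e-8)
    }
  }
})

test_that("matrix TSV and JSON serializations roundtrip", {
  b <- basis(fig1())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(b$alpha, path)
  back <- read_matrix_tsv(path)
  expect_true(all(back == b$alpha))
  expect_identical(rownames(back), rownames(b$alpha))

  js <- jsonlite::fromJSON(matrix_to_json(b$gamma, rate = "gamma"))
  expect_identical(js$rate, "gamma")
  expect_true(all(js$rows == unname(b$gamma)))
})
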