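test_that("priority vectors match closed forms and a power-iteration oracle", {
  # consistent 2x2 closed form
  pv <- priority_vector(matrix(c(1, 0.5, 2, 1), 2, 2))
  expect_equal(unname(pv$weights), c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(pv$lambda_max, 2, tolerance = 1e-9)

  # all-ones: uniform by symmetry
  pv1 <- priority_vector(matrix(1, 4, 4))
  expect_equal(unname(pv1$weights), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(pv1$lambda_max, 4, tolerance = 1e-9)

  # inconsistent 3x3 against an independent power-iteration oracle
  P <- rbind(c(1, 2, 6), c(1 / 2, 1, 4), c(1 / 6, 1 / 4, 1))
  pv3 <- priority_vector(P)
  o <- power_iteration_oracle(P)
  expect_equal(unname(pv3$weights), o$weights, tolerance = 1e-10)
  expect_equal(pv3$lambda_max, o$lambda_max, tolerance = 1e-10)
  expect_gte(pv3$lambda_max, 3 - 1e-9)
  expect_equal(sum(pv3$weights), 1, tolerance = 1e-12)

  expect_error(priority_vector(rbind(c(1, 2), c(0.9, 1))), "reciprocal")
})

test_that("consistency reports CI, RI, CR with the documented conventions", {
  # any ratio-constructed matrix is perfectly consistent
  w <- c(0.5, 0.3, 0.2)
  P <- outer(w, w, "/")
  cr <- consistency(P)
  expect_equal(cr$CR, 0, tolerance = 1e-9)
  expect_true(cr$pass)
  expect_equal(unname(priority_vector(P)$weights), w, tolerance = 1e-9)

  # m = 2: CR defined 0
  expect_equal(consistency(matrix(c(1, 1 / 3, 3, 1), 2, 2))$CR, 0)

  # inconsistent 3x3: CR from lambda_max via the formula, same eigen oracle
  P3 <- rbind(c(1, 2, 6), c(1 / 2, 1, 4), c(1 / 6, 1 / 4, 1))
  lam <- power_iteration_oracle(P3)$lambda_max
  expect_equal(consistency(P3)$CR, ((lam - 3) / 2) / 0.58, tolerance = 1e-9)

  # order beyond the RI table
  big <- diag(16); big[upper.tri(big)] <- 1; big[lower.tri(big)] <- 1
  expect_error(consistency(big), "decompose")
})

test_that("network construction derives edges, sources and sinks", {
  fx <- drowning_fixtures()
  net <- fixture_network(fx)
  expect_setequal(net$sources, c("F1", "F8", "F15", "F16"))
  expect_setequal(net$sinks, c("F4", "F5", "F18"))
  expect_setequal(net$clusters,
                  c("host", "medium", "physical environment",
                    "social environment"))

  # identity: no edges, everything both source and sink
  ident <- diag(2L); dimnames(ident) <- list(c("a", "b"), c("a", "b"))
  net0 <- build_network(ident, c(a = "c1", b = "c1"))
  expect_equal(nrow(net0$edges), 0)
  expect_setequal(net0$sources, c("a", "b"))
  expect_setequal(net0$sinks, c("a", "b"))

  expect_error(build_network(ident, c(a = "c1")), "unclustered")
})

test_that("unweighted supermatrix columns hold priority vectors of target sets", {
  m <- rbind(c(1L, 1L), c(0L, 1L))
  dimnames(m) <- list(c("F1", "F2"), c("F1", "F2"))
  net <- build_network(m, c(F1 = "c", F2 = "c"))
  w0 <- assemble_unweighted(net, list())
  # single-target column and sink self-loop
  expect_equal(bare(w0), rbind(c(0, 0), c(1, 1)))
  expect_equal(colSums(w0), c(F1 = 1, F2 = 1))

  # 2-target criterion with judgment [[1,3],[1/3,1]] -> 0.75 / 0.25
  m3 <- rbind(c(1L, 1L, 1L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  dimnames(m3) <- list(c("j", "a", "b"), c("j", "a", "b"))
  net3 <- build_network(m3, c(j = "c", a = "c", b = "c"))
  J <- matrix(c(1, 1 / 3, 3, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  w03 <- assemble_unweighted(net3, list(j = J))
  expect_equal(w03["a", "j"], 0.75, tolerance = 1e-9)
  expect_equal(w03["b", "j"], 0.25, tolerance = 1e-9)
  expect_equal(unname(colSums(w03)), rep(1, 3), tolerance = 1e-12)

  # missing or mismatched judgment matrices are named
  expect_error(assemble_unweighted(net3, list()), "criterion j")
  Jbad <- matrix(1, 2, 2, dimnames = list(c("a", "x"), c("a", "x")))
  expect_error(assemble_unweighted(net3, list(j = Jbad)), "expects")
})

test_that("cluster weighting scales blocks and renormalizes columns", {
  m3 <- rbind(c(1L, 1L, 1L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  dimnames(m3) <- list(c("j", "a", "b"), c("j", "a", "b"))
  cl <- c(j = "c1", a = "c2", b = "c2")
  net3 <- build_network(m3, cl)
  J <- matrix(c(1, 1 / 3, 3, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  w0 <- assemble_unweighted(net3, list(j = J))

  # uniform fallback: column c2 fed by c2 alone (sink self-loops) -> entry 1;
  # single feeding cluster gets weight 1
  a_unif <- cluster_weight_matrix(w0, net3)
  expect_equal(a_unif["c2", "c1"], 1)
  expect_equal(a_unif["c2", "c2"], 1)

  # 2:1 comparison between the two clusters linked to column cluster c1
  m4 <- rbind(c(1L, 1L, 1L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  dimnames(m4) <- list(c("u", "a", "t"), c("u", "a", "t"))
  cl4 <- c(u = "c1", a = "c2", t = "c3")
  net4 <- build_network(m4, cl4)
  Ju <- matrix(1, 2, 2, dimnames = list(c("a", "t"), c("a", "t")))
  w04 <- assemble_unweighted(net4, list(u = Ju))
  cj <- list(c1 = matrix(c(1, 0.5, 2, 1), 2, 2,
                         dimnames = list(c("c2", "c3"), c("c2", "c3"))))
  a4 <- cluster_weight_matrix(w04, net4, cj)
  expect_equal(a4["c2", "c1"], 2 / 3, tolerance = 1e-9)
  expect_equal(a4["c3", "c1"], 1 / 3, tolerance = 1e-9)
  # mismatched comparison set is refused
  cjbad <- list(c1 = matrix(1, 2, 2, dimnames = list(c("c1", "c2"),
                                                     c("c1", "c2"))))
  expect_error(cluster_weight_matrix(w04, net4, cjbad), "linked")

  # blockwise product oracle: elementwise multiply then renormalize
  w4 <- apply_cluster_weights(w04, a4, cl4)
  expect_equal(attr(w4, "stage"), "weighted")
  manual <- w04
  for (i in rownames(w04)) {
    for (j in colnames(w04)) {
      manual[i, j] <- w04[i, j] * a4[cl4[[i]], cl4[[j]]]
    }
  }
  manual <- sweep(manual, 2, colSums(manual), "/")
  expect_equal(bare(w4), bare(manual), tolerance = 1e-12)
  expect_equal(unname(colSums(w4)), rep(1, 3), tolerance = 1e-9)

  # single cluster, all-ones normalized: W unchanged
  a1 <- matrix(1, 1, 1, dimnames = list("c", "c"))
  w0s <- assemble_unweighted(
    build_network(rbind(c(1L, 1L), c(0L, 1L)) |>
                    `dimnames<-`(list(c("x", "y"), c("x", "y"))),
                  c(x = "c", y = "c")), list())
  expect_equal(bare(apply_cluster_weights(w0s, a1, c(x = "c", y = "c"))),
               bare(w0s))
})

test_that("limit supermatrix converges, absorbs, or falls back to Cesaro", {
  # identity converges immediately
  li <- limit_supermatrix(diag(3))
  expect_equal(bare(li), diag(3))
  expect_equal(attr(li, "method"), "power")

  # absorbing 2-chain: all transient mass ends at the sink
  w <- matrix(c(0, 1, 0, 1), 2, 2)
  la <- limit_supermatrix(w)
  expect_equal(bare(la), matrix(c(0, 1, 0, 1), 2, 2), tolerance = 1e-12)
  # power-limit idempotence
  expect_lt(max(abs(la %*% w - la)), 1e-8)

  # period-2 permutation: Cesaro average, all entries 0.5
  perm <- matrix(c(0, 1, 1, 0), 2, 2)
  lp <- limit_supermatrix(perm, max_squarings = 50)
  expect_equal(attr(lp, "method"), "cesaro")
  expect_equal(bare(lp), matrix(0.5, 2, 2), tolerance = 1e-12)

  expect_error(limit_supermatrix(matrix(c(0.2, 0.2, 0.5, 0.5), 2, 2)),
               "stochastic")
})

test_that("global weights take agreeing columns or renormalized row means", {
  # identity limit: uniform weights, shared smaller rank
  gw <- global_weights(structure(diag(2), dimnames = list(c("a", "b"),
                                                          c("a", "b"))))
  expect_equal(gw$weight, c(0.5, 0.5))
  expect_equal(gw$rank, c(1L, 1L))

  # absorbing chain: sink 1, transient 0
  la <- limit_supermatrix(matrix(c(0, 1, 0, 1), 2, 2))
  gwa <- global_weights(la)
  expect_equal(gwa$weight, c(0, 1))
  expect_equal(gwa$rank, c(2L, 1L))
  expect_equal(sum(gwa$weight), 1, tolerance = 1e-9)
})

test_that("the pipeline equals manual stage composition and is deterministic", {
  fx <- drowning_fixtures()
  net <- fixture_network(fx)
  j <- seeded_judgments(net, seed = 7)

  res <- anp_pipeline(net, j)
  w0 <- assemble_unweighted(net, j)
  a <- cluster_weight_matrix(w0, net)
  wm <- apply_cluster_weights(w0, a, net$cluster_of)
  lim <- limit_supermatrix(wm)
  expect_equal(res$weights, global_weights(lim))
  expect_equal(unname(res$limit), unname(lim))

  # bit-identical rerun
  res2 <- anp_pipeline(net, seeded_judgments(net, seed = 7))
  expect_identical(res$weights, res2$weights)

  # weighted supermatrix column-stochastic; weights sum to 1
  expect_equal(unname(colSums(res$W)), rep(1, 18), tolerance = 1e-9)
  expect_equal(sum(res$weights$weight), 1, tolerance = 1e-9)

  # consistent-by-construction judgments all pass the gate
  expect_true(all(vapply(res$consistency, `[[`, logical(1), "pass")))

  # an inconsistent judgment matrix is refused by name
  jbad <- j
  tg <- rownames(jbad[[1]])[1:4]
  # cyclic preferences: maximally incoherent, CR far above the gate
  Pbad <- matrix(1, 4, 4, dimnames = list(tg, tg))
  for (cyc in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    Pbad[cyc[1], cyc[2]] <- 9
    Pbad[cyc[2], cyc[1]] <- 1 / 9
  }
  expect_gt(consistency(Pbad)$CR, 0.1)
  jbad[[1]] <- Pbad
  expect_error(anp_pipeline(net, jbad), names(jbad)[1])
  # ... unless overridden
  resb <- anp_pipeline(net, jbad, allow_inconsistent = TRUE)
  expect_s3_class(resb, "anp_result")
})

test_that("scale invariance: rank-one reciprocal perturbations shift 2x2 priorities", {
  w <- c(0.7, 0.3)
  P <- outer(w, w, "/")
  v <- c(2, 5)
  Pv <- P * outer(v, v, "/")
  got <- priority_vector(Pv)$weights
  want <- (w * v) / sum(w * v)
  expect_equal(unname(got), want, tolerance = 1e-9)
})
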