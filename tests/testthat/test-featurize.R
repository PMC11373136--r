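test_that("descriptor generation yields one finite named row per compound", {
  m <- compute_descriptors("CCO", "physchem_descriptors")
  expect_equal(nrow(m), 1)
  expect_gte(ncol(m), 20)
  expect_true(all(is.finite(m)))
  expect_false(anyDuplicated(colnames(m)) > 0)
  # molecular weight of ethanol: 2*12.011 + 6*1.008 + 15.999
  expect_equal(unclass(m)[1, "MW"], 46.07, tolerance = 1e-3)
})

test_that("descriptors are a pure function of structure", {
  m <- compute_descriptors(c("CCO", "c1ccccc1O", "CCO"), "extended_descriptors")
  expect_equal(unclass(m)[1, ], unclass(m)[3, ])
  expect_false(isTRUE(all.equal(unclass(m)[1, ], unclass(m)[2, ])))
})

test_that("row permutation permutes descriptor rows identically", {
  smis <- c("CCO", "CCN", "c1ccccc1O", "CC(C)C", "CCCC[N+](=O)[O-]")
  perm <- c(3, 1, 5, 2, 4)
  m1 <- compute_descriptors(smis, "extended_descriptors")
  m2 <- compute_descriptors(smis[perm], "extended_descriptors")
  expect_equal(unclass(m1)[perm, ], unclass(m2)[, ], ignore_attr = TRUE)
})

test_that("extended descriptors are graph-only and include topological indices", {
  m <- compute_descriptors(c("CCO", "c1ccc2ccccc2c1"), "extended_descriptors")
  expect_true(all(c("Wiener", "BalabanJ", "ZagrebM1", "Randic") %in% colnames(m)))
  # Wiener index of ethanol C-C-O path graph: d(1,2)+d(1,3)+d(2,3)=1+2+1
  expect_equal(unclass(m)[1, "Wiener"], 4)
  # naphthalene: 10 heavy atoms, 11 bonds -> Zagreb M1 = sum deg^2 = 2*3^2+8*2^2
  expect_equal(unclass(m)[2, "ZagrebM1"], 50)
})

test_that("circular fingerprints are binary, deterministic, with frozen popcount", {
  fp <- morgan_fingerprints(c("CCO", "CCO"), radius = 2, n_bits = 2048)
  expect_true(all(fp %in% c(0, 1)))
  expect_equal(unclass(fp)[1, ], unclass(fp)[2, ])
  pc <- sum(fp[1, ])
  expect_equal(pc, 9)                 # frozen from one run of the hashing scheme
  expect_gte(pc, 1); expect_lte(pc, 20)
  fp0 <- morgan_fingerprints("C", radius = 0, n_bits = 2048)
  expect_gte(sum(fp0), 1)
})

test_that("fingerprint folding preserves determinism across n_bits", {
  a <- morgan_fingerprints("c1ccccc1O", n_bits = 512)
  b <- morgan_fingerprints("c1ccccc1O", n_bits = 512)
  expect_identical(unclass(a), unclass(b))
  expect_equal(ncol(a), 512)
})

test_that("cleaning drops exactly the defective columns, in order", {
  m <- feature_matrix(matrix(c(1, 2, 3, NA, 5, 6, 7, 8, 9), 3,
                             dimnames = list(NULL, c("a", "b", "c"))),
                      "physchem_descriptors")
  cl <- clean_features(m)
  expect_identical(colnames(cl), c("a", "c"))
  expect_identical(attr(cl, "dropped"), "b")
  # identity on defect-free input
  ok <- feature_matrix(matrix(1:9, 3, dimnames = list(NULL, c("a", "b", "c"))),
                       "physchem_descriptors")
  expect_equal(unclass(clean_features(ok))[, ], unclass(ok)[, ])
  # Inf counts as defective
  m2 <- feature_matrix(matrix(c(1, Inf, 3, 4), 2, dimnames = list(NULL, c("u", "v"))),
                       "physchem_descriptors")
  expect_identical(colnames(clean_features(m2)), "v")
  expect_error(clean_features(feature_matrix(
    matrix(NA_real_, 2, 1, dimnames = list(NULL, "z")), "physchem_descriptors")),
    class = "featurization_error")
})

test_that("cleaning a multi-molecule extended matrix leaves no non-finite entries", {
  rows <- rule_labeled_smiles(n_molecules = 50, seed = 17)
  cd <- curate_compounds(rows)
  m <- compute_descriptors(cd, "extended_descriptors")
  n_bad <- sum(apply(unclass(m), 2, function(col) any(!is.finite(col))))
  cl <- clean_features(m)
  expect_equal(ncol(cl), ncol(m) - n_bad)    # independent defective-column scan
  expect_true(all(is.finite(cl)))
})

test_that("min-max scaling endpoints, constant columns, and clipping", {
  tr <- feature_matrix(matrix(c(2, 4, 6, 5, 5, 5), 3,
                              dimnames = list(NULL, c("a", "const"))),
                       "physchem_descriptors")
  st <- fit_minmax(tr)
  sc <- apply_minmax(st, tr)
  expect_equal(unclass(sc)[, "a"], c(0, 0.5, 1))
  expect_equal(unclass(sc)[, "const"], c(0, 0, 0))
  te <- feature_matrix(matrix(c(-5, 15, 5, 5), 2,
                              dimnames = list(NULL, c("a", "const"))),
                       "physchem_descriptors")
  expect_equal(unclass(apply_minmax(st, te))[, "a"], c(0, 1))
  bad <- feature_matrix(matrix(1:4, 2, dimnames = list(NULL, c("x", "y"))),
                        "physchem_descriptors")
  expect_error(apply_minmax(st, bad), class = "schema_error")
})

test_that("scaling maps non-constant training columns onto [0,1] exactly", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- matrix(rnorm(40 * 6), 40, 6)
      colnames(x) <- letters[1:6]
      fm <- feature_matrix(x, "physchem_descriptors")
      sc <- apply_minmax(fit_minmax(fm), fm)
      expect_equal(unname(apply(unclass(sc), 2, min)), rep(0, 6))
      expect_equal(unname(apply(unclass(sc), 2, max)), rep(1, 6))
    }
  })
})

test_that("fingerprint matrices pass through cleaning and scaling unchanged", {
  fp <- morgan_fingerprints(c("CCO", "c1ccccc1O", "CCN"), n_bits = 256)
  cl <- clean_features(fp)
  expect_equal(unclass(cl)[, ], unclass(fp)[, ])
  sc <- apply_minmax(fit_minmax(cl), cl)
  expect_equal(unclass(sc)[, colnames(cl)], unclass(cl)[, ])
})

test_that("combined descriptor matrices prefix names by kind", {
  a <- clean_features(compute_descriptors(c("CCO", "CCN"), "physchem_descriptors"))
  b <- clean_features(compute_descriptors(c("CCO", "CCN"), "extended_descriptors"))
  comb <- combine_features(a, b)
  expect_equal(ncol(comb), ncol(a) + ncol(b))
  expect_true(all(grepl("^(phys|exte)\\.", colnames(comb))))
})
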