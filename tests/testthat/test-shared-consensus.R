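mini_cci <- function(ligands, targets = "t1", cancer = "c1") {
  data.frame(cancer = cancer, sender = "fibroblast", ligand = ligands,
             receiver = "cancer cell",
             target = rep(targets, length.out = length(ligands)),
             weight = 1, activity = 0.5, stringsAsFactors = FALSE)
}

test_that("universal URs is the strict intersection across cancers", {
  cci <- list(mini_cci(c("a", "b", "c")), mini_cci(c("a", "b")),
              mini_cci(c("a", "b", "d")), mini_cci(c("a", "b")),
              mini_cci(c("b", "e")))
  # "a" present in 4 of 5 cancers: excluded
  expect_equal(universal_urs(cci), "b")
  # identical sets replicated: everything retained
  same <- replicate(5, mini_cci(c("x", "y")), simplify = FALSE)
  expect_equal(universal_urs(same), c("x", "y"))
  # random sets match the set-intersection oracle
  set.seed(17)
  for (i in 1:20) {
    sets <- lapply(1:5, function(k) sample(letters, sample(3:10, 1)))
    cci_r <- lapply(sets, mini_cci)
    expect_equal(universal_urs(cci_r),
                 sort(Reduce(intersect, sets)))
  }
})

deg_row <- function(cancer, ct, gene, fc) {
  data.frame(cancer = cancer, cell_type = ct, gene = gene, log2fc = fc,
             adj_p = 0.01, stringsAsFactors = FALSE)
}

test_that("direction concordance implements the 4-of-5 majority rule", {
  # signs (+,+,+,+,-) in fibroblast: retained with n_concordant 4
  tabs <- lapply(1:5, function(k) {
    deg_row(sprintf("c%d", k), "fibroblast", "g", c(1, 1, 1, 1, -1)[k])
  })
  res <- direction_concordance("g", tabs, min_concordant = 4)
  expect_equal(res,
               data.frame(cell_type = "fibroblast", sign = 1L,
                          n_concordant = 4L, stringsAsFactors = FALSE))

  # signs (+,+,-,-) plus one cancer missing the gene: nothing retained
  tabs2 <- c(lapply(1:4, function(k) {
    deg_row(sprintf("c%d", k), "fibroblast", "g", c(1, 1, -1, -1)[k])
  }), list(deg_row("c5", "fibroblast", "other", 1)))
  expect_equal(nrow(direction_concordance("g", tabs2, 4)), 0)

  # log2fc of exactly 0 counts toward neither sign
  tabs3 <- lapply(1:5, function(k) {
    deg_row(sprintf("c%d", k), "fibroblast", "g", c(1, 1, 1, 0, 0)[k])
  })
  expect_equal(nrow(direction_concordance("g", tabs3, 4)), 0)
  expect_equal(direction_concordance("g", tabs3, 3)$n_concordant, 3L)

  # gene absent everywhere: empty result
  expect_equal(nrow(direction_concordance("nope", tabs, 4)), 0)
})

test_that("direction concordance equals the brute-force tally oracle", {
  set.seed(23)
  for (rep in 1:30) {
    tabs <- lapply(1:5, function(k) {
      n <- sample(5:15, 1)
      tab <- data.frame(
        cancer = sprintf("c%d", k),
        cell_type = sample(paste0("ct", 1:4), n, TRUE),
        gene = sample(sprintf("g%d", 1:6), n, TRUE),
        log2fc = sample(c(-1, 1), n, TRUE) * runif(n, 0.3, 2),
        adj_p = 0.01, stringsAsFactors = FALSE)
      tab[!duplicated(tab[, c("cell_type", "gene")]), ]
    })
    for (g in sprintf("g%d", 1:6)) {
      expect_equal(canon(direction_concordance(g, tabs, 3)),
                   canon(oracle_concordance(g, tabs, 3)))
    }
  }
})

test_that("shared-MCTM recovers exactly the planted structure", {
  cfg <- sim_config(seed = 29)
  degs <- generate_deg_tables(cfg)
  prior <- generate_prior(cfg)
  cci <- lapply(degs, infer_cci_for_cancer, prior = prior)
  sm <- build_shared_mctm(cci, degs)
  lay <- shmctm:::sim_layout(cfg)
  expect_setequal(unique(sm$shared_urs$gene), lay$planted_urs)
  expect_setequal(unique(sm$shared_dss$gene), lay$planted_ds)
  expect_true(all(sm$shared_urs$cell_type == "fibroblast"))
  expect_true(all(sm$shared_dss$cell_type == "cancer cell"))
  expect_equal(length(sm$genes),
               length(lay$planted_urs) + length(lay$planted_ds))
  expect_true(all(sm$edges$n_shared_ds >= 1))
})

test_that("degenerate consensus inputs behave as specified", {
  cfg <- sim_config(seed = 29)
  degs <- generate_deg_tables(cfg)
  cci <- lapply(degs, infer_cci_for_cancer, prior = generate_prior(cfg))
  # single-cancer input: consensus undefined
  expect_error(build_shared_mctm(cci[1], degs[1]), ">= 2 cancers")
  # threshold above the cancer count: empty model with a warning
  expect_warning(sm <- build_shared_mctm(cci, degs, min_concordant = 6),
                 "no shared-URs")
  expect_equal(length(sm$genes), 0)
  expect_equal(nrow(sm$edges), 0)
})

test_that("consensus is monotone in min_concordant and order-invariant", {
  set.seed(37)
  inst <- random_consensus_instance()
  fit <- function(mc) suppressWarnings(
    build_shared_mctm(inst$cci_sets, inst$deg_tables, min_concordant = mc))
  sm4 <- fit(4)
  sm3 <- fit(3)
  sm2 <- fit(2)
  key <- function(x) paste(x$shared_urs$gene, x$shared_urs$cell_type)
  expect_true(all(key(sm4) %in% key(sm3)))
  expect_true(all(key(sm3) %in% key(sm2)))

  perm <- c(3, 1, 5, 2, 4)
  sm_perm <- suppressWarnings(
    build_shared_mctm(inst$cci_sets[perm], inst$deg_tables[perm],
                      min_concordant = 2))
  expect_equal(canon(sm2$shared_urs), canon(sm_perm$shared_urs))
  expect_equal(canon(sm2$shared_dss), canon(sm_perm$shared_dss))
  expect_equal(canon(sm2$edges), canon(sm_perm$edges))
})

test_that("shared-MCTM equals the brute-force nested-loop oracle", {
  set.seed(41)
  for (rep in 1:25) {
    inst <- random_consensus_instance(n_genes = 30, p_deg = 0.3)
    mc <- sample(2:4, 1)
    sm <- suppressWarnings(
      build_shared_mctm(inst$cci_sets, inst$deg_tables,
                        min_concordant = mc))
    oracle <- oracle_shared_mctm(inst$cci_sets, inst$deg_tables,
                                 min_concordant = mc)
    expect_equal(canon(sm$shared_urs), canon(oracle$shared_urs))
    expect_equal(canon(sm$shared_dss), canon(oracle$shared_dss))
    expect_equal(canon(sm$edges), canon(oracle$edges))
  }
})

test_that("shared-MCTM serialization writes genes, edges and a summary", {
  cfg <- sim_config(seed = 29)
  degs <- generate_deg_tables(cfg)
  cci <- lapply(degs, infer_cci_for_cancer, prior = generate_prior(cfg))
  sm <- build_shared_mctm(cci, degs)
  prefix <- tempfile()
  paths <- write_shared_mctm(sm, prefix)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[3])
  expect_equal(js$n_genes, length(sm$genes))
  expect_equal(js$n_shared_urs, length(unique(sm$shared_urs$gene)))
})
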