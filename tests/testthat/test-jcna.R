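# correlated block: optionally heterogeneous module membership (hub-like)
make_block <- function(J, n, rho) {
  common <- rnorm(n)
  t(sapply(seq_len(J), function(i)
    sqrt(rho) * common + sqrt(1 - rho) * rnorm(n)))
}
make_block_hub <- function(J, n, rmin = 0.2, rmax = 0.95) {
  common <- rnorm(n)
  rho <- runif(J, rmin, rmax)
  t(sapply(seq_len(J), function(i)
    sqrt(rho[i]) * common + sqrt(1 - rho[i]) * rnorm(n)))
}

test_that("sample outlier removal keeps homogeneous cohorts intact", {
  set.seed(91)
  expr <- matrix(rnorm(50 * 20), 50, 20,
                 dimnames = list(paste0("j", 1:50), paste0("s", 1:20)))
  expect_gte(length(remove_outlier_samples(expr, min_samples = 10)), 19L)
  # one sample shifted far away is removed, and only that one
  expr_o <- expr
  expr_o[, 5] <- expr_o[, 5] + 50
  kept <- remove_outlier_samples(expr_o, min_samples = 10)
  expect_identical(setdiff(colnames(expr), kept), "s5")
  # identical samples: nothing to remove
  same <- matrix(1:50, 50, 8, dimnames = list(paste0("j", 1:50),
                                              paste0("s", 1:8)))
  expect_equal(remove_outlier_samples(same, min_samples = 5),
               colnames(same))
})

test_that("good_features drops exactly the engineered bad junctions", {
  set.seed(92)
  expr <- matrix(rnorm(100 * 12), 100, 12,
                 dimnames = list(paste0("j", 1:100), NULL))
  expr[3, 1:8] <- NA          # 67% missing
  expr[50, ] <- 7             # constant
  expr[97, 1:7] <- NA         # 58% missing
  kept <- good_features(expr)
  expect_identical(setdiff(rownames(expr), kept), c("j3", "j50", "j97"))
})

test_that("adjacency follows its closed form and an element-wise oracle", {
  cc <- matrix(c(1, 1, -1, 0,
                 1, 1, 0.5, 0,
                 -1, 0.5, 1, 0.3,
                 0, 0, 0.3, 1), 4, 4)
  for (b in c(1, 4, 7)) {
    a <- adjacency_matrix(cor_mat = cc, power = b, type = "unsigned")
    expect_equal(a[1, 2], 1)       # cor +1
    expect_equal(a[1, 3], 1)       # cor -1, unsigned
    expect_equal(a[1, 4], 0)       # cor 0
    expect_equal(a[2, 3], 0.5^b)
  }
  s <- adjacency_matrix(cor_mat = cc, power = 2, type = "signed")
  expect_equal(s[1, 3], 0)         # cor -1, signed
  set.seed(93)
  expr <- matrix(rnorm(6 * 15), 6, 15, dimnames = list(paste0("j", 1:6), NULL))
  a6 <- adjacency_matrix(expr, power = 5, type = "unsigned",
                         method = "pearson")
  oracle <- abs(cor(t(expr)))^5; diag(oracle) <- 1
  expect_equal(a6, oracle, tolerance = 1e-15)
})

test_that("TOM matches closed forms and the brute-force triple loop", {
  # 2-node network: no shared neighbors, TOM = adjacency
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  expect_equal(tom_similarity(a2)[1, 2], 0.4)
  # complete graph with unit weights: TOM = 1 everywhere
  a1 <- matrix(1, 5, 5)
  expect_true(all(tom_similarity(a1) == 1))
  # random 20-node adjacency vs triple loop
  set.seed(94)
  r <- matrix(runif(400), 20, 20)
  a <- (r + t(r)) / 2; diag(a) <- 1
  tom <- tom_similarity(a)
  expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom))
})

test_that("soft threshold: noise is flagged, hub-structured data reach target", {
  cfg <- network_config()
  set.seed(95)
  noise <- matrix(rnorm(100 * 25), 100, 25,
                  dimnames = list(paste0("j", 1:100), NULL))
  sft_n <- suppressWarnings(pick_soft_threshold(noise, cfg))
  expect_false(sft_n$target_reached)   # noise networks are not scale-free
  # mean connectivity strictly decreasing in the power
  expect_true(all(diff(sft_n$table$mean_k) < 0))
  # planted modules with graded membership reach the target at a low power
  set.seed(96)
  expr <- do.call(rbind, lapply(c(80, 50, 35, 25, 20),
                                function(sz) make_block_hub(sz, 50)))
  rownames(expr) <- paste0("j", seq_len(nrow(expr)))
  sft <- pick_soft_threshold(expr, cfg)
  expect_true(sft$target_reached)
  expect_lte(sft$chosen_power, 12)
  expect_gte(sft$table$sft_r2[sft$table$power == sft$chosen_power], 0.8)
  noise[1, ] <- 1
  expect_error(pick_soft_threshold(noise, cfg), "good_features")
})

test_that("planted two-block networks are recovered as two pure modules", {
  set.seed(61)
  n <- 30
  expr <- rbind(make_block(30, n, 0.8), make_block(30, n, 0.8))
  rownames(expr) <- paste0("j", 1:60)
  truth <- rep(1:2, each = 30)
  cfg <- network_config()
  tom <- tom_similarity(adjacency_matrix(expr, power = 6, method = "bicor"))
  mods <- detect_modules(1 - tom, cfg, expr = expr)
  expect_equal(length(unique(mods$labels[mods$labels != 0])), 2L)
  expect_lte(sum(mods$labels == 0), 2L)                # at most 2 mislabels
  expect_gte(adjusted_rand_index(mods$labels, truth), 0.9)
  expect_true(all(table(mods$labels[mods$labels != 0]) >=
                    cfg$min_module_size))
})

test_that("noise stays unassigned and tiny inputs yield no modules", {
  set.seed(97)
  noise <- matrix(rnorm(100 * 30), 100, 30,
                  dimnames = list(paste0("j", 1:100), NULL))
  tom <- tom_similarity(adjacency_matrix(noise, power = 6))
  mods <- detect_modules(1 - tom, network_config(), expr = noise)
  expect_gte(mean(mods$labels == 0), 0.9)
  small <- matrix(rnorm(5 * 10), 5, 10, dimnames = list(paste0("j", 1:5),
                                                        NULL))
  expect_warning(
    m0 <- detect_modules(1 - tom_similarity(adjacency_matrix(small,
                                                             power = 6)),
                         network_config()),
    "min_module_size")
  expect_true(all(m0$labels == 0))
})

test_that("eigengenes match a direct spectral oracle and orient consistently", {
  set.seed(98)
  n <- 25
  expr <- make_block(20, n, 0.7)
  rownames(expr) <- paste0("j", 1:20)
  labels <- setNames(rep(1L, 20), rownames(expr))
  eg <- module_eigengenes(expr, labels)
  # oracle: full SVD of the standardized member matrix
  sc <- t(scale(t(expr)))
  sv <- svd(sc)
  expect_equal(unname(eg$var_explained),
               sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  expect_gte(cor(eg$eigengenes[, 1], colMeans(sc)), 0)
  expect_true(all(abs(eg$membership) <= 1))
  # module of identical profiles: ME is that profile, var explained 1
  same <- matrix(rep(rnorm(n), each = 4), 4, n,
                 dimnames = list(paste0("j", 1:4), NULL))
  eg1 <- module_eigengenes(same, setNames(rep(1L, 4), rownames(same)))
  expect_equal(unname(eg1$var_explained), 1)
  expect_equal(abs(cor(eg1$eigengenes[, 1], same[1, ])), 1)
  # flipping all member profiles flips the ME with the orientation rule
  egf <- module_eigengenes(-same, setNames(rep(1L, 4), rownames(same)))
  expect_equal(unname(egf$var_explained), 1)
  expect_equal(egf$eigengenes[, 1], -eg1$eigengenes[, 1])
})

test_that("module-trait correlations match the direct formula", {
  set.seed(99)
  n <- 40
  expr <- rbind(make_block(25, n, 0.8), make_block(25, n, 0.8))
  rownames(expr) <- paste0("j", 1:50)
  tom <- tom_similarity(adjacency_matrix(expr, power = 6))
  mods <- detect_modules(1 - tom, network_config(), expr = expr)
  eg <- module_eigengenes(expr, mods)
  traits <- data.frame(t1 = eg$eigengenes[, 1],
                       t2 = rnorm(n))
  mt <- module_trait_correlation(eg, traits)
  expect_equal(unname(mt$cor["ME1", "t1"]), 1)
  # hand formula on an arbitrary cell
  r <- cor(eg$eigengenes[, 2], traits$t2)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(unname(mt$p["ME2", "t2"]), 2 * pt(-abs(tt), n - 2),
               tolerance = 1e-12)
})

test_that("independent traits rarely reach significance against eigengenes", {
  set.seed(100)
  n <- 40
  expr <- rbind(make_block(25, n, 0.8), make_block(25, n, 0.8))
  rownames(expr) <- paste0("j", 1:50)
  mods <- detect_modules(
    1 - tom_similarity(adjacency_matrix(expr, power = 6)),
    network_config(), expr = expr)
  eg <- module_eigengenes(expr, mods)
  hits <- replicate(200, {
    mt <- module_trait_correlation(eg, data.frame(t = rnorm(n)))
    any(mt$fdr < 0.05)
  })
  # expected no-hit rate >= 95%, allow 3 binomial SEs below
  expect_gte(mean(!hits), 0.95 - 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("two-pass filter separates gene-driven from splicing-driven signal", {
  set.seed(81)
  n <- 60; n_genes <- 50; jpg <- 4
  G <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("G%02d", 1:n_genes), paste0("s", 1:n)))
  host <- rep(rownames(G), each = jpg)
  junc <- G[host, ] + matrix(rnorm(length(host) * n, 0, 0.7),
                             length(host), n)
  rownames(junc) <- paste0(host, ".j", sequence(rep(jpg, n_genes)))
  spl <- rnorm(n)   # independent splicing signal on one junction of G02
  junc["G02.j1", ] <- G["G02", ] * 0.3 + spl * 1.2 + rnorm(n, 0, 0.3)
  # trait proportional to gene G01 expression: its junctions inherit the
  # correlation and are dropped as gene-driven
  tp_g <- two_pass_filter(junc, G, host,
                          as.numeric(scale(G["G01", ])) + rnorm(n, 0, 0.3))
  expect_gte(mean(!tp_g$kept[tp_g$gene_id == "G01"]), 0.9)
  # trait following the splicing signal: that junction is kept
  tp_s <- two_pass_filter(junc, G, host, spl + rnorm(n, 0, 0.4))
  expect_true(tp_s$kept[tp_s$junction_id == "G02.j1"])
  expect_lte(sum(tp_s$kept), nrow(junc))
  expect_identical(two_pass_filter(junc, G, host, spl + 0 * spl)$kept,
                   two_pass_filter(junc, G, host, spl)$kept)  # deterministic
  # GS values are absolute correlations
  expect_true(all(tp_s$gs_junction >= 0 & tp_s$gs_junction <= 1))
  expect_error(two_pass_filter(junc, G, c("NOPE", host[-1]), spl),
               "absent from gene expression")
})

test_that("a null trait keeps about the 2-SD Gaussian tail fraction", {
  set.seed(82)
  n <- 80; n_genes <- 125; jpg <- 4
  G <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("G%03d", 1:n_genes), NULL))
  host <- rep(rownames(G), each = jpg)
  junc <- G[host, ] + matrix(rnorm(length(host) * n, 0, 0.7),
                             length(host), n)
  rownames(junc) <- paste0(host, ".j", sequence(rep(jpg, n_genes)))
  tp <- two_pass_filter(junc, G, host, rnorm(n))
  expect_gt(mean(tp$kept), 0.046 - 0.025)
  expect_lt(mean(tp$kept), 0.046 + 0.025)
})

test_that("edge lists respect the weight floor and ordering contract", {
  tom <- matrix(c(1, 0.5, 0.2,
                  0.5, 1, 0.05,
                  0.2, 0.05, 1), 3, 3,
                dimnames = rep(list(c("jB", "jA", "jC")), 2))
  labels <- setNames(c(1L, 1L, 0L), c("jB", "jA", "jC"))
  dir <- tempfile()
  out <- export_network(tom, labels, dir, weight_min = 0.1)
  expect_equal(nrow(out$edges), 2L)   # weights {0.5, 0.2} pass, 0.05 fails
  expect_true(all(out$edges$source < out$edges$target))
  expect_true(file.exists(out$files["cytoscape"]))
  vis <- read.delim(out$files["visant"], header = FALSE)
  expect_equal(nrow(vis), 2L)
  expect_true(all(vis$V3 == 0))
  # floor above every off-diagonal weight: header-only edge file
  out0 <- export_network(tom, labels, dir, weight_min = 1.0,
                         prefix = "empty")
  expect_equal(nrow(out0$edges), 0L)
  lines <- readLines(out0$files["cytoscape"])
  expect_equal(length(lines), 1L)
  expect_match(lines, "^source\ttarget")
})

test_that("the one-pass pipeline is deterministic and the 2-pass reruns", {
  set.seed(101)
  n <- 30
  expr <- rbind(make_block(30, n, 0.8), make_block(25, n, 0.8))
  rownames(expr) <- paste0("j", seq_len(nrow(expr)))
  colnames(expr) <- paste0("s", 1:n)
  cfg <- network_config()
  r1 <- suppressWarnings(run_jcna(expr, cfg, power = 6))
  r2 <- suppressWarnings(run_jcna(expr, cfg, power = 6))
  expect_identical(r1$modules$labels, r2$modules$labels)
  expect_identical(r1$tom, r2$tom)
  expect_equal(length(unique(r1$modules$labels[r1$modules$labels != 0])), 2L)
})
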