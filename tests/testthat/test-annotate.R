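make_library <- function(...) {
  entries <- list(...)
  data.frame(name = vapply(entries, `[[`, "", "name"),
             superfamily = vapply(entries, `[[`, "", "superfamily"),
             family = vapply(entries, `[[`, "", "family"),
             te_class = vapply(entries, function(e)
               repeatscape:::classify_superfamily(e$superfamily), ""),
             sequence = vapply(entries, `[[`, "", "sequence"),
             stringsAsFactors = FALSE)
}

test_that("cluster annotation votes by best hit with plurality labeling", {
  withr::local_seed(12)
  lib <- make_library(
    list(name = "RLG-1", superfamily = "Gypsy", family = "RLG_x",
         sequence = rand_seq(800)),
    list(name = "RLC-1", superfamily = "Copia", family = "RLC_y",
         sequence = rand_seq(800)))
  reads_a <- vapply(1:10, function(i) {
    st <- sample(1:700, 1); substr(lib$sequence[1], st, st + 99)
  }, "")
  ann <- annotate_cluster(reads_a, lib)
  expect_equal(ann$family, "RLG_x")
  expect_equal(ann$superfamily, "Gypsy")
  expect_equal(ann$hit_fraction, 1.0)

  mixed <- c(reads_a[1:6], vapply(1:4, function(i) {
    st <- sample(1:700, 1); substr(lib$sequence[2], st, st + 99)
  }, ""))
  ann2 <- annotate_cluster(mixed, lib)
  expect_equal(ann2$family, "RLG_x")
  expect_equal(ann2$hit_fraction, 0.6)

  rnd <- vapply(rep(100, 5), rand_seq, "")
  ann3 <- annotate_cluster(rnd, lib)
  expect_equal(ann3$family, "unannotated")
  expect_equal(ann3$hit_fraction, 0)
  # exhaustive DP oracle: no qualifying 55 bp / 90 % alignment exists
  expect_true(all(vapply(rnd, function(r)
    sw_oracle_score(r, lib$sequence[1]), 0) < 55 * 0.9 - 6 * 4))
})

test_that("composition converts cluster sizes into conserved fractions", {
  mk_ann <- function(fam, sf, hf, size) {
    structure(list(family = fam, superfamily = sf, te_class = "Class I LTR",
                   hit_fraction = hf, vote_breakdown = integer(),
                   cluster_size = size), class = "cluster_annotation")
  }
  cl <- structure(list(clusters = list(CL1 = paste0("r", 1:200)),
                       unclustered = character(), membership = NULL,
                       merge_log = NULL), class = "cluster_set")
  comp <- composition(cl, list(mk_ann("X", "Gypsy", 1.0, 200)), 1000)
  expect_equal(comp$fraction[comp$family == "X"], 0.20)
  expect_equal(sum(comp$fraction), 1.0)

  comp2 <- composition(cl, list(mk_ann("X", "Gypsy", 0.5, 200)), 1000)
  expect_equal(comp2$fraction[comp2$family == "X"], 0.10)
  expect_equal(comp2$fraction[comp2$family == "unannotated"], 0.10)
  expect_equal(sum(comp2$fraction), 1.0)

  cl3 <- structure(list(clusters = list(CL1 = paste0("a", 1:100),
                                        CL2 = paste0("b", 1:50)),
                        unclustered = character(), membership = NULL,
                        merge_log = NULL), class = "cluster_set")
  comp3 <- composition(cl3, list(mk_ann("Y", "Copia", 1.0, 100),
                                 mk_ann("Y", "Copia", 1.0, 50)), 1000)
  expect_equal(comp3$fraction[comp3$family == "Y"], 0.15)

  expect_error(composition(cl3, list(mk_ann("Y", "Copia", 1, 100),
                                     mk_ann("Y", "Copia", 1, 50)), 100),
               "exceed")
})

test_that("composition is invariant under cluster relabeling", {
  mk_ann <- function(fam, hf, size) {
    structure(list(family = fam, superfamily = "Gypsy",
                   te_class = "Class I LTR", hit_fraction = hf,
                   vote_breakdown = integer(), cluster_size = size),
              class = "cluster_annotation")
  }
  cl_a <- structure(list(clusters = list(CL1 = paste0("r", 1:60),
                                         CL2 = paste0("s", 1:40)),
                         unclustered = character()), class = "cluster_set")
  cl_b <- structure(list(clusters = list(ZZ9 = paste0("r", 1:60),
                                         AA1 = paste0("s", 1:40)),
                         unclustered = character()), class = "cluster_set")
  anns <- list(mk_ann("F1", 0.9, 60), mk_ann("F2", 0.8, 40))
  ca <- composition(cl_a, anns, 200)
  cb <- composition(cl_b, anns, 200)
  expect_equal(ca, cb)
})

test_that("replicates with identical seeds give SD exactly zero", {
  fam <- data.frame(name = "RLG-1", superfamily = "Gypsy", family = "RLG_x",
                    consensus_length = 1000, copy_number = 10,
                    divergence = 0.01, indel_rate = 0,
                    stringsAsFactors = FALSE)
  gen <- make_genome(genome_spec(50000, fam, seed = 3))
  reads <- simulate_reads(gen, coverage = 2, insert_mean = 300,
                          insert_sd = 20, error_rate = 0, seed = 4)
  comp <- replicate_composition(reads, gen$library, k = 150,
                                seeds = c(7, 7, 7))
  expect_true(all(comp$sd == 0))
  expect_true(all(abs(comp$mean - comp$rep1) < 1e-12))
  # single replicate: SD is reported as NA, not 0
  comp1 <- replicate_composition(reads, gen$library, k = 150, seeds = 7)
  expect_true(all(is.na(comp1$sd)))
  # conservation per replicate
  expect_equal(sum(comp$rep1), 1.0)
})

test_that("coverage titration reports per-level CV with hand arithmetic", {
  # sample SD / mean of (0.1, 0.2, 0.3) is 0.5: the CV definition under test
  expect_equal(stats::sd(c(0.1, 0.2, 0.3)) / mean(c(0.1, 0.2, 0.3)), 0.5)
  fam <- data.frame(name = "RLG-1", superfamily = "Gypsy", family = "RLG_x",
                    consensus_length = 1000, copy_number = 10,
                    divergence = 0.01, indel_rate = 0,
                    stringsAsFactors = FALSE)
  gen <- make_genome(genome_spec(50000, fam, seed = 3))
  reads <- simulate_reads(gen, coverage = 2, insert_mean = 300,
                          insert_sd = 20, error_rate = 0, seed = 4)
  tit <- coverage_titration(reads, gen$library, levels = c(0.2),
                            genome_length = 50000, seeds = c(5, 5, 5))
  expect_equal(tit$pairs, 50L)
  expect_equal(tit$mean_cv, 0)  # identical replicate compositions
  expect_error(coverage_titration(reads, gen$library, levels = 5,
                                  genome_length = 50000), "available")
})
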