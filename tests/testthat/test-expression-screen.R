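# GMT I/O, keyword selection, probe aggregation, relative expression and
# the consistent-direction screen with its brute-force oracle.

test_that("GMT files round-trip losslessly", {
  coll <- gene_set_collection(list(
    list(name = "SET_A", description = "first set",
         genes = c("A", "B", "C")),
    list(name = "SET_B", description = "second set",
         genes = c("B", "C", "D", "E"))))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path)
  expect_equal(back$sets, coll$sets)
})

test_that("GMT parsing agrees with an independent reader", {
  skip_if_not_installed("fgsea")
  coll <- generate_gene_sets(sprintf("G%03d", 1:100), n_sets = 8L,
                             membership_range = c(5L, 30L), seed = 13L)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  ours <- read_gmt(path)
  theirs <- fgsea::gmtPathways(path)
  expect_equal(set_names(ours), names(theirs))
  for (nm in names(theirs))
    expect_equal(ours$sets[[match(nm, set_names(ours))]]$genes,
                 unname(theirs[[nm]]))
})

test_that("malformed and duplicated GMT content is handled", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tA\tB", "SET_B\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2")
  writeLines("SET_A\tdesc\tA\tB\tA\tC", path)
  expect_warning(back <- read_gmt(path), "1 duplicated")
  expect_equal(back$sets[[1]]$genes, c("A", "B", "C"))
})

test_that("keyword selection is case-insensitive and order-preserving", {
  coll <- gene_set_collection(list(
    list(name = "GOBP_GLUCOSE_IMPORT", description = "x", genes = "A"),
    list(name = "GOBP_PANCREAS_DEVELOPMENT",
         description = "response to glucose", genes = "B"),
    list(name = "GOBP_LIPID_STORAGE", description = "fat", genes = "C")))
  expect_equal(set_names(select_gene_sets(coll, "GLUCOSE")),
               set_names(select_gene_sets(coll, "glucose")))
  expect_length(select_gene_sets(coll, "glucose"), 2L)
  expect_length(select_gene_sets(coll, "glucose", fields = "name"), 1L)
  expect_length(select_gene_sets(coll, "ribosome"), 0L)
  expect_error(select_gene_sets(coll, ""), "non-empty")
})

test_that("gene union preserves first-appearance order and uniqueness", {
  coll <- gene_set_collection(list(
    list(name = "S1", description = "", genes = c("A", "B", "C")),
    list(name = "S2", description = "", genes = c("B", "C", "D"))))
  expect_equal(union_genes(coll), c("A", "B", "C", "D"))
  single <- gene_set_collection(list(
    list(name = "S", description = "", genes = c("X", "Y"))))
  expect_equal(union_genes(single), c("X", "Y"))
})

test_that("gene union size matches a brute-force union on random sets", {
  set.seed(7)
  uni <- sprintf("G%03d", 1:60)
  for (i in 1:20) {
    sets <- lapply(1:5, function(j)
      list(name = paste0("S", j), description = "",
           genes = sample(uni, sample(3:30, 1))))
    coll <- gene_set_collection(sets)
    expect_setequal(union_genes(coll),
                    Reduce(union, lapply(sets, `[[`, "genes")))
  }
})

test_that("probe aggregation averages probes and drops unmapped ones", {
  mat <- matrix(c(10, 30, 7, 100,
                  20, 40, 8, 200), nrow = 4,
                dimnames = list(c("p1", "p2", "p3", "px"), c("s1", "s2")))
  samples <- data.frame(sample = c("s1", "s2"), line = "L1",
                        condition = c("adhesion", "suspension"))
  map <- data.frame(probe = c("p1", "p2", "p3"),
                    gene = c("GA", "GA", "GB"))
  study <- expression_study(mat, samples, probe_map = map)
  expect_message(agg <- aggregate_probes(study), "1 unmapped")
  expect_equal(agg$matrix["GA", ], c(s1 = 20, s2 = 30))
  expect_equal(agg$matrix["GB", ], c(s1 = 7, s2 = 8))
  # permuting probe rows changes nothing
  study2 <- expression_study(mat[c(3, 1, 4, 2), , drop = FALSE], samples,
                             probe_map = map)
  expect_message(agg2 <- aggregate_probes(study2))
  expect_equal(agg2$matrix, agg$matrix)
  expect_error(aggregate_probes(
    expression_study(mat, samples, probe_map = NULL)), "probe map")
})

test_that("relative expression is the fractional suspension change", {
  adh <- matrix(1000, nrow = 2, ncol = 3,
                dimnames = list(c("G1", "G2"), NULL))
  susp <- matrix(c(340, 1000), nrow = 2, ncol = 3,
                 dimnames = list(c("G1", "G2"), NULL))
  rel <- relative_expression_table(tiny_study(adh, susp))
  expect_equal(rel$r[rel$gene == "G1"], rep(-0.66, 2))
  expect_equal(sprintf("%+.1f%%", 100 * rel$r[rel$gene == "G1"][1]),
               "-66.0%")
  expect_equal(rel$r[rel$gene == "G2"], rep(0, 2))
})

test_that("zero adhesion intensity flags the entry as undefined", {
  adh <- matrix(c(0, 10), nrow = 2, ncol = 2,
                dimnames = list(c("G1", "G2"), NULL))
  susp <- matrix(5, nrow = 2, ncol = 2,
                 dimnames = list(c("G1", "G2"), NULL))
  rel <- relative_expression_table(tiny_study(adh, susp))
  expect_true(all(is.nan(rel$r[rel$gene == "G1"])))
  expect_true(all(rel$undefined[rel$gene == "G1"]))
})

test_that("screen matches the brute-force per-gene scan", {
  set.seed(11)
  for (i in 1:60) {
    n_g <- sample(5:25, 1)
    r <- matrix(rnorm(n_g * 4, sd = 0.2), nrow = n_g,
                dimnames = list(sprintf("g%02d", seq_len(n_g)),
                                paste0("L", 1:4)))
    tau <- sample(c(0, 0.05, 0.1), 1)
    res <- consistent_direction_screen(make_r_table(r), rownames(r),
                                       tau = tau)
    oracle <- brute_force_screen(r, tau)
    expect_identical(res$down, oracle$down)
    expect_identical(res$up, oracle$up)
  }
})

test_that("a single discordant line vetoes a consistent call", {
  r <- matrix(c(-0.05, -0.05, -0.05, 0.01), nrow = 1,
              dimnames = list("g1", paste0("L", 1:4)))
  res <- consistent_direction_screen(make_r_table(r), "g1", tau = 0)
  expect_length(res$down, 0L)
  expect_length(res$up, 0L)
})

test_that("strict inequalities leave exact zeros uncalled", {
  r <- matrix(0, nrow = 3, ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("L", 1:4)))
  res <- consistent_direction_screen(make_r_table(r), rownames(r), tau = 0)
  expect_length(res$down, 0L)
  expect_length(res$up, 0L)
})

test_that("screen calls shrink monotonically as tau grows", {
  set.seed(5)
  r <- matrix(rnorm(200, sd = 0.3), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), paste0("L", 1:4)))
  tab <- make_r_table(r)
  taus <- c(0, 0.05, 0.1, 0.2, 0.5)
  prev <- consistent_direction_screen(tab, rownames(r), taus[1])
  for (tau in taus[-1]) {
    cur <- consistent_direction_screen(tab, rownames(r), tau)
    expect_true(all(cur$down %in% prev$down))
    expect_true(all(cur$up %in% prev$up))
    prev <- cur
  }
})

test_that("relative expression is invariant to per-line rescaling", {
  sim <- generate_expression_study(
    expression_sim_spec(sprintf("G%02d", 1:20), c("L1", "L2"),
                        planted_down = "G01", seed = 14L))
  study <- sim$study
  rel_a <- relative_expression_table(study)
  scaled <- study
  l1 <- study$samples$sample[study$samples$line == "L1"]
  scaled$matrix[, l1] <- scaled$matrix[, l1] * 3.7
  rel_b <- relative_expression_table(scaled)
  expect_equal(rel_b$r, rel_a$r)
})

test_that("universe genes without complete measurements are excluded", {
  r <- matrix(-0.2, nrow = 2, ncol = 4,
              dimnames = list(c("g1", "g2"), paste0("L", 1:4)))
  tab <- make_r_table(r)
  tab <- tab[!(tab$gene == "g2" & tab$line == "L4"), ]
  class(tab) <- c("relative_expression_table", "data.frame")
  expect_message(res <- consistent_direction_screen(tab, c("g1", "g2", "g3")),
                 "excluded")
  expect_equal(res$universe, "g1")
  expect_equal(res$down, "g1")
  expect_error(consistent_direction_screen(tab, character(0)), "empty")
})

test_that("transporter panel formats and marks the reference pattern", {
  ref <- transporter_reference()
  r <- matrix(NA_real_, nrow = 4, ncol = 4,
              dimnames = list(unique(ref$gene), unique(ref$line)))
  for (i in seq_len(nrow(ref))) r[ref$gene[i], ref$line[i]] <- ref$effect[i]
  pan <- transporter_panel(make_r_table(r))
  cell <- function(g, ln) pan[pan$gene == g & pan$line == ln, ]
  expect_equal(cell("SLC16A3", "A375")$percent, "-62.7%")
  expect_true(cell("SLC16A3", "A375")$marked)
  expect_equal(cell("SLC16A3", "A2058")$percent, "-28.6%")
  expect_false(cell("SLC16A3", "A2058")$marked)
  expect_equal(cell("SLC16A1", "A2058")$percent, "+0.6%")
  expect_false(cell("SLC16A1", "A2058")$marked)
  expect_true(cell("SLC2A1", "RPMI7951")$marked)  # -38.4% just over 0.35
  # missing panel gene yields a blank, warned cell
  r2 <- r[-3, , drop = FALSE]
  w <- capture_warnings(pan2 <- transporter_panel(make_r_table(r2)))
  expect_length(w, 4L)
  expect_true(all(grepl("missing", w)))
  expect_equal(pan2$percent[pan2$gene == "SLC16A3"], rep("", 4))
})
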