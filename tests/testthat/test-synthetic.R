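test_that("simulation is byte-deterministic under a fixed seed and config", {
  cfg <- small_config(seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$fold, b$truth$fold)
  pa <- simulate_promoters(cfg, a$truth)
  pb <- simulate_promoters(cfg, b$truth)
  expect_identical(as.character(pa$promoters$seq), as.character(pb$promoters$seq))
  ka <- simulate_peaks(cfg, pa$truth)
  kb <- simulate_peaks(cfg, pb$truth)
  expect_identical(ka$peaks, kb$peaks)
})

test_that("planted programs are disjoint, counts valid, NT and nulls silent", {
  cfg <- small_config(seed = 3)
  sim <- simulate_counts(cfg)
  counts <- sim$counts$counts
  expect_true(all(counts >= 0))
  expect_true(is.integer(counts))
  # every gene carries exactly one class label; programs partition the genome
  expect_identical(sort(names(sim$truth$class)), sort(sim$truth$genes))
  # NT never responds: true fold change 1 for every gene
  expect_true(all(sim$truth$fold[, cfg$nt_line] == 1))
  # null genes respond in no line
  nulls <- sim$truth$genes[sim$truth$class == "null"]
  expect_true(all(sim$truth$fold[nulls, ] == 1))
  # class sizes match the configuration
  base <- sub(":.*$", "", sim$truth$class)
  expect_equal(sum(base == "common_up"), cfg$program_sizes$common_up)
  expect_equal(sum(base == "gof_shared_up"), cfg$program_sizes$gof_shared_up)
  expect_equal(sum(sim$truth$class == "private_up:T419R"),
               unname(cfg$program_sizes$private_up["T419R"]))
})

test_that("a null configuration plants no responsive gene anywhere", {
  sim <- simulate_counts(null_config(seed = 5, n_genes = 300))
  expect_true(all(sim$truth$fold == 1))
  expect_true(all(sim$truth$baseline == 1))
})

test_that("planted fold structure follows the configured effects", {
  cfg <- small_config(n_genes = 2000, seed = 2)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  common <- tr$genes[tr$class == "common_up"]
  # WT common folds average the configured 5.4 (exact-mean jitter, n = 45)
  expect_equal(mean(tr$fold[common, "WT"]), 5.4, tolerance = 0.1)
  # GOF amplification is the exact configured per-line multiplier
  for (ln in c("R274W", "R321S", "N574I")) {
    expect_equal(tr$fold[common, ln] / tr$fold[common, "WT"],
                 rep(1.4, length(common)), ignore_attr = TRUE)
  }
  expect_equal(tr$fold[common, "T419R"] / tr$fold[common, "WT"],
               rep(6.4 / 5.4, length(common)), ignore_attr = TRUE)
  shared <- tr$genes[tr$class == "gof_shared_up"]
  expect_true(all(tr$fold[shared, "WT"] == 1))
  expect_equal(mean(tr$fold[shared, "R274W"]), 4.5, tolerance = 0.15)
  # mixed genes respond in >= 2 lines but never in the exact all-GOF pattern
  mixed <- tr$genes[tr$class == "mixed_up"]
  for (g in mixed) {
    resp <- colnames(tr$fold)[tr$fold[g, ] > 1]
    expect_gte(length(resp), 2)
    expect_false(setequal(resp, cfg$gof_lines))
  }
})

test_that("empirical stimulated/unstimulated count ratios recover planted folds", {
  cfg <- sim_config(seed = 1)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  counts <- sim$counts$counts
  meta <- sim$counts$meta
  common <- tr$genes[tr$class == "common_up"]
  stim <- meta$sample[meta$line == "WT" & meta$condition == "stim"]
  unstim <- meta$sample[meta$line == "WT" & meta$condition == "unstim"]
  m_s <- rowMeans(counts[common, stim])
  m_u <- rowMeans(counts[common, unstim])
  keep <- m_u >= 200
  expect_gt(sum(keep), 5)
  expect_equal(mean(m_s[keep] / m_u[keep]), 5.4, tolerance = 0.15 * 5.4)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 100), "exceed")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(peak_policy = c(canonical = 1.2, degenerate = 0.4,
                                          absent = 0.05)), "peak_policy")
  expect_error(sim_config(motif_consensus = "A", promoter_upstream = 0,
                          promoter_downstream = 0), "window|promoter")
})

test_that("motif planting obeys the per-class policy", {
  cfg <- small_config(n_genes = 600, seed = 9)
  sim <- simulate_counts(cfg)
  pr <- simulate_promoters(cfg, sim$truth)
  tr <- pr$truth
  base <- sub(":.*$", "", tr$class)
  # absent policy classes carry no planted motif
  expect_true(all(is.na(tr$motif$start[base %in% c("null", "private_up", "mixed_up")])))
  # canonical copies are exact consensus inside the placement window
  canon <- which(base == "common_up")
  expect_true(all(tr$motif$mismatches[canon] == 0))
  expect_true(all(tr$motif$word[canon] == cfg$motif_consensus))
  expect_true(all(tr$motif$start[canon] >= -100 & tr$motif$start[canon] < 0))
  # degenerate copies have the promised Hamming distance
  cons <- strsplit(cfg$motif_consensus, "")[[1]]
  degen <- which(base == "gof_shared_up")
  hd <- vapply(tr$motif$word[degen], function(w) {
    sum(strsplit(w, "")[[1]] != cons)
  }, numeric(1))
  expect_identical(unname(hd), as.numeric(tr$motif$mismatches[degen]))
  expect_true(all(hd %in% 1:2))
  # planted words really are in the sequences at the recorded positions
  for (i in canon[1:5]) {
    s <- as.character(pr$promoters$seq[[i]])
    pos <- tr$motif$start[i] + cfg$promoter_upstream + 1
    expect_identical(substr(s, pos, pos + 8), cfg$motif_consensus)
  }
})

test_that("single-mismatch policy plants at Hamming distance exactly one", {
  cfg <- small_config(
    n_genes = 300, seed = 13,
    motif_policy = list(
      common_up = list(type = "degenerate", mismatches = 1, window = c(-100, 0)),
      default = list(type = "absent")
    )
  )
  sim <- simulate_counts(cfg)
  pr <- simulate_promoters(cfg, sim$truth)
  cons <- strsplit(cfg$motif_consensus, "")[[1]]
  words <- pr$truth$motif$word[!is.na(pr$truth$motif$word)]
  expect_gt(length(words), 0)
  hd <- vapply(words, function(w) sum(strsplit(w, "")[[1]] != cons), numeric(1))
  expect_true(all(hd == 1))
})

test_that("peak placement follows the per-class policy probabilities", {
  cfg <- small_config(n_genes = 300, seed = 4,
                      peak_policy = c(canonical = 0, degenerate = 0, absent = 0))
  sim <- simulate_counts(cfg)
  pr <- simulate_promoters(cfg, sim$truth)
  pk <- simulate_peaks(cfg, pr$truth)
  expect_equal(nrow(pk$peaks), 0)

  cfg1 <- small_config(n_genes = 300, seed = 4,
                       peak_policy = c(canonical = 1, degenerate = 1, absent = 1))
  pk1 <- simulate_peaks(cfg1, simulate_promoters(cfg1, simulate_counts(cfg1)$truth)$truth)
  windows <- promoter_windows(pk1$truth$layout)
  expect_true(all(overlaps_peak(windows, pk1$peaks)))

  # canonical-class peak rate within the binomial 99% CI of 0.9 at n = 1000
  cfg2 <- sim_config(n_genes = 1000, seed = 6,
                     program_sizes = list(common_up = 1000, gof_shared_up = 0,
                                          mixed_up = 0, wt_only_up = 0,
                                          private_up = c(R274W = 0, R321S = 0,
                                                         T419R = 0, N574I = 0),
                                          down = c(WT = 0), baseline_up = c(T419R = 0),
                                          baseline_down = c(T419R = 0)))
  pk2 <- simulate_peaks(cfg2, simulate_promoters(cfg2, simulate_counts(cfg2)$truth)$truth)
  frac <- sum(!is.na(pk2$truth$peaks$start)) / 1000
  ci <- qnorm(0.995) * sqrt(0.9 * 0.1 / 1000)
  expect_lt(abs(frac - 0.9), ci)
})

test_that("simulate_to_dir writes a round-trippable file set", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n_genes = 120, seed = 8)
  paths <- simulate_to_dir(cfg, dir)
  expect_true(all(file.exists(paths)))
  cm <- read_counts(paths["counts"], paths["meta"])
  sim <- simulate_counts(cfg)
  expect_identical(cm$counts, sim$counts$counts)
  pr <- read_promoters(paths["promoters"])
  pr0 <- simulate_promoters(cfg, sim$truth)$promoters
  expect_identical(as.character(pr$seq), as.character(pr0$seq))
  expect_identical(pr$layout$strand, pr0$layout$strand)
  pk <- read_peaks(paths["peaks"])
  pk0 <- simulate_peaks(cfg, simulate_promoters(cfg, sim$truth)$truth)$peaks
  expect_identical(pk[, c("contig", "start", "end")],
                   as.data.frame(pk0)[, c("contig", "start", "end")],
                   ignore_attr = TRUE)
})
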