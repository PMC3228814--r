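test_that("classification follows the category rule table", {
  ref <- tiny_ref()
  check <- function(events) {
    read <- apply_events(ref$seq, events)
    aln <- align_read(read, ref)
    cls <- classify_read(aln, ref)
    expect_equal(cls$category,
                 oracle_classify(aln$events$event_type, aln$events$length))
    cls
  }
  # zero events
  expect_equal(check(NULL)$category, "accurate")
  # one homopolymer G insertion
  runs <- homopolymer_runs(ref$seq)
  g2 <- runs[runs$base == "G" & runs$len >= 2, ][1, ]
  cls <- check(ins_event(g2$start, "G"))
  expect_equal(cls$category, "single_insertion")
  expect_true(cls$frameshift)
  # 2-nt run extension plus one distant random insertion = multi_insertion
  cls <- check(rbind(ins_event(g2$start, "GG"), ins_event(200, "G")))
  expect_equal(cls$category, "multi_insertion")
  expect_equal(cls$total_nt_changed, 3L)
  expect_false(cls$frameshift)  # net +3 nt keeps the frame
  # insertion + substitution = mixed
  cls <- check(rbind(ins_event(50, "A"), sub_event(ref$seq, 200, "A")))
  expect_equal(cls$category, "mixed")
  # single deletion / substitution
  expect_equal(check(del_event(ref$seq, 40))$category, "single_deletion")
  old <- substr(ref$seq, 41, 41)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  expect_equal(check(sub_event(ref$seq, 40, new))$category,
               "single_substitution")
})

test_that("classification matches the rule-table oracle on random event sets", {
  ref <- tiny_ref()
  set.seed(61)
  for (i in 1:60) {
    n_ev <- sample(0:3, 1)
    pos <- sort(sample(seq(10, ref$length - 10, by = 9), n_ev))
    events <- NULL
    for (p in pos) {
      tp <- sample(c("insertion", "deletion", "substitution"), 1)
      ev <- switch(tp,
        insertion = ins_event(p, random_seq(sample(1:2, 1))),
        deletion = del_event(ref$seq, p),
        substitution = sub_event(ref$seq, p,
          sample(setdiff(c("A", "C", "G", "T"),
                         substr(ref$seq, p + 1, p + 1)), 1)))
      events <- rbind(events, ev)
    }
    read <- apply_events(ref$seq, events)
    aln <- align_read(read, ref)
    expect_equal(classify_read(aln, ref)$category,
                 oracle_classify(aln$events$event_type,
                                 aln$events$length))
  }
})

test_that("partial alignments are rejected by the classifier", {
  ref <- tiny_ref()
  aln <- align_read(substr(ref$seq, 1, ref$length - 10), ref)
  expect_error(classify_read(aln, ref), "full")
})

test_that("region assignment matches an interval-membership scan", {
  ref <- tiny_ref()
  rg <- ref$regions
  for (p in c(0L, sample(0:(ref$length - 1), 60))) {
    got <- assign_region(ins_event(p, "G"), ref)
    exp <- rg$region[rg$start <= p & p < rg$end]
    expect_equal(got, exp, info = p)
  }
  expect_equal(assign_region(ins_event(0, "G"), ref), "FR1")
  # boundary insertion belongs to the region starting there
  expect_equal(assign_region(ins_event(rg$start[2], "G"), ref), "CDR1")
  expect_error(assign_region(ins_event(ref$length + 5, "G"), ref),
               "outside")
})

test_that("composition deltas count bases and conserve length differences", {
  ref <- tiny_ref()
  # single G insertion: dG = 1, others 0
  read <- apply_events(ref$seq, ins_event(80, "G"))
  expect_equal(composition_delta(read, ref),
               c(dA = 0L, dG = 1L, dT = 0L, dC = 0L))
  # accurate read: all zero
  expect_equal(sum(abs(composition_delta(ref$seq, ref))), 0L)
  # random edits against a direct counting oracle
  set.seed(71)
  for (i in 1:40) {
    s <- random_seq(30)
    r <- random_seq(sample(25:35, 1))
    d <- composition_delta(r, s)
    cnt <- function(x, b) lengths(regmatches(x, gregexpr(b, x)))
    for (b in c("A", "G", "T", "C"))
      expect_equal(d[[paste0("d", b)]], cnt(r, b) - cnt(s, b))
    expect_equal(sum(d), nchar(r) - nchar(s))
  }
})

test_that("recurrent signatures report grouped frequencies", {
  ref <- tiny_ref()
  runs <- homopolymer_runs(ref$seq)
  g2 <- runs[runs$base == "G" & runs$len >= 2, ][1, ]
  # 100 erroneous reads, one signature repeated 7 times
  reads <- character(0)
  for (i in 1:7)
    reads <- c(reads, apply_events(ref$seq, ins_event(g2$start, "G")))
  set.seed(73)
  pool <- setdiff(seq(10, ref$length - 10), g2$start)
  for (p in sample(pool, 93)) {
    old <- substr(ref$seq, p + 1, p + 1)
    reads <- c(reads, apply_events(
      ref$seq, sub_event(ref$seq, p, sample(setdiff(c("A", "C", "G", "T"),
                                                    old), 1))))
  }
  names(reads) <- sprintf("r%03d", seq_along(reads))
  batch <- classify_reads(reads, ref)
  sig <- recurrent_signatures(batch, min_frac = 0.005)
  expect_equal(sig$n_reads[1], 7L)
  expect_equal(sig$frac[1], 0.07)
  # composition-only grouping merges all single-G insertions
  sigc <- recurrent_signatures(batch, min_frac = 0.05, by = "composition")
  g_row <- grepl("dA=+0,dG=+1,dT=+0,dC=+0", sigc$signature, fixed = TRUE)
  expect_equal(sigc$n_reads[g_row], 7L)
  # all-accurate input gives an empty table
  acc <- classify_reads(setNames(rep(ref$seq, 3), c("a", "b", "c")), ref)
  expect_equal(nrow(recurrent_signatures(acc)), 0)
})

test_that("profile summary percentages and totals are consistent", {
  ref <- tiny_ref()
  sim <- simulate_reads(ref, sim_config(n_reads = 400, seed = 79))
  batch <- classify_reads(sim$reads, ref)
  prof <- summarize_profile(batch, ref)
  expect_equal(sum(prof$categories$n), 400L)
  expect_lt(abs(sum(prof$categories$pct) - 100), 0.31)  # 6 roundings
  ins <- batch$events[batch$events$event_type == "insertion", ]
  expect_equal(sum(prof$regions$n_insertions), sum(!is.na(ins$region)))
  expect_equal(sum(prof$inserted_bases$n), sum(ins$length))
  # homopolymer table counts cover all indel-only erroneous reads
  cls <- batch$classifications
  n_indel_only <- sum(cls$category %in%
    c("single_insertion", "multi_insertion", "single_deletion")) +
    sum(cls$category == "mixed" & cls$read_id %in%
          setdiff(batch$events$read_id,
                  batch$events$read_id[
                    batch$events$event_type == "substitution"]))
  expect_equal(sum(prof$homopolymer_table$n_reads), n_indel_only)
})

test_that("classifier recovers the configured mixture (synthetic replica)", {
  ref <- tiny_ref()
  cfg <- sim_config(n_reads = 2000, seed = 83)
  sim <- simulate_reads(ref, cfg)
  batch <- classify_reads(sim$reads, ref)
  prof <- summarize_profile(batch, ref)
  for (cc in names(cfg$p)) {
    p <- cfg$p[[cc]]
    got <- prof$categories$n[prof$categories$category == cc] / 2000
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(got - p), 3 * se + 1e-12, )
  }
  # classified category equals the planted category read by read
  truth_cat <- sim$truth$category[!duplicated(sim$truth$read_id)]
  names(truth_cat) <- sim$truth$read_id[!duplicated(sim$truth$read_id)]
  cls <- batch$classifications
  expect_gte(mean(cls$category == truth_cat[cls$read_id]), 0.995)
})

test_that("degenerate all-G insertion profile reports 100% G", {
  ref <- tiny_ref()
  cfg <- sim_config(p_accurate = 0, p_single_ins = 1, p_multi_ins = 0,
                    p_single_del = 0, p_single_sub = 0, p_mixed = 0,
                    insertion_base_probs = c(A = 0, C = 0, G = 1, T = 0),
                    n_reads = 80, seed = 89)
  sim <- simulate_reads(ref, cfg)
  batch <- classify_reads(sim$reads, ref)
  prof <- summarize_profile(batch, ref)
  expect_equal(prof$inserted_bases$frac[prof$inserted_bases$base == "G"], 1)
})
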