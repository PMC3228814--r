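test_that("the error-free reference is productive", {
  ref <- tiny_ref()
  fun <- assess_functionality(ref$seq, ref)
  expect_equal(fun$verdict, "productive")
  expect_true(fun$in_frame)
  expect_true(fun$conserved_ok)
  expect_length(fun$stop_codons, 0)
})

test_that("an in-frame TAA substitution is called stop_codon", {
  ref <- tiny_ref()
  # find a codon that one substitution turns into TAA
  cods <- substring(ref$seq, seq(1, ref$length - 2, 3),
                    seq(3, ref$length, 3))
  k <- which(substr(cods, 1, 1) == "T" & substr(cods, 2, 2) == "A" &
               substr(cods, 3, 3) != "A" & substr(cods, 3, 3) != "G")[1]
  expect_false(is.na(k))
  pos <- 3L * (k - 1L) + 2L  # 0-based position of the third codon base
  read <- apply_events(ref$seq, sub_event(ref$seq, pos, "A"))
  fun <- assess_functionality(read, ref)
  expect_equal(fun$verdict, "stop_codon")
  expect_true(k %in% fun$stop_codons)
})

test_that("frameshifting indels match a translate-and-scan oracle", {
  ref <- tiny_ref()
  set.seed(101)
  for (i in 1:25) {
    p <- sample(seq(12, ref$length - 12), 1)
    ev <- if (runif(1) < 0.5) ins_event(p, random_seq(1))
          else del_event(ref$seq, p)
    read <- apply_events(ref$seq, ev)
    fun <- assess_functionality(read, ref)
    expect_false(fun$verdict == "productive")  # net 1 nt is never in frame
    # oracle: translate the read in frame 0 and scan for stops
    aa <- Biostrings::translate(Biostrings::DNAString(
      substr(read, 1, 3 * (nchar(read) %/% 3))), no.init.codon = TRUE)
    has_stop <- grepl("*", as.character(aa), fixed = TRUE)
    expect_equal(fun$verdict == "stop_codon", has_stop)
  }
})

test_that("a homopolymer insertion read is fully corrected and recovered", {
  ref <- tiny_ref()
  runs <- homopolymer_runs(ref$seq)
  g3 <- runs[runs$base == "G" & runs$len >= 2, ][1, ]
  read <- apply_events(ref$seq, ins_event(g3$start, "G"))
  res <- correct_read(read, ref)
  expect_identical(res$corrected_seq, ref$seq)
  expect_equal(nrow(res$applied_edits), 1)
  expect_false(res$functionality_before == "productive")
  expect_equal(res$functionality_after, "productive")
  expect_true(res$recovered)
})

test_that("correcting an accurate read applies zero edits (idempotence)", {
  ref <- tiny_ref()
  res <- correct_read(ref$seq, ref)
  expect_equal(nrow(res$applied_edits), 0)
  expect_false(res$recovered)
  expect_equal(res$functionality_before, "productive")
  # correcting a corrected read is a no-op
  read <- apply_events(ref$seq, rbind(ins_event(40, "G"),
                                      del_event(ref$seq, 90)))
  once <- correct_read(read, ref)
  twice <- correct_read(once$corrected_seq, ref)
  expect_equal(nrow(twice$applied_edits), 0)
  expect_identical(twice$corrected_seq, once$corrected_seq)
})

test_that("deletion + insertion 30 nt apart are both repaired", {
  ref <- tiny_ref()
  events <- rbind(del_event(ref$seq, 60), ins_event(90, "A"))
  read <- apply_events(ref$seq, events)
  res <- correct_read(read, ref)
  expect_equal(nrow(res$applied_edits), 2)
  expect_equal(res$functionality_after, "productive")
  expect_equal(nchar(res$corrected_seq), ref$length)
  # inverse of the truth log: the pad sits at the deletion's canonical
  # coordinate and stripping it restores the reference minus one base
  dpos <- res$applied_edits$ref_pos[res$applied_edits$event_type ==
                                      "deletion"]
  expect_equal(substr(res$corrected_seq, dpos + 1, dpos + 1), "n")
  no_pad <- gsub("n", "", res$corrected_seq)
  expect_identical(no_pad, paste0(substr(ref$seq, 1, 60),
                                  substr(ref$seq, 62, ref$length)))
})

test_that("substitutions are never altered by correction (safety)", {
  ref <- tiny_ref()
  set.seed(107)
  for (i in 1:15) {
    p_sub <- sample(seq(12, ref$length - 12), 1)
    old <- substr(ref$seq, p_sub + 1, p_sub + 1)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    p_ins <- ((p_sub + 40) %% (ref$length - 24)) + 12
    read <- apply_events(ref$seq, rbind(
      sub_event(ref$seq, p_sub, new),
      ins_event(p_ins, sample(c("A", "C", "G", "T"), 1))))
    res <- correct_read(read, ref)
    expect_equal(substr(res$corrected_seq, p_sub + 1, p_sub + 1), new)
  }
})

test_that("all indel-only erroneous reads become productive after correction", {
  ref <- tiny_ref()
  cfg <- sim_config(p_accurate = 0, p_single_ins = 0.4, p_multi_ins = 0.3,
                    p_single_del = 0.3, p_single_sub = 0, p_mixed = 0,
                    n_reads = 120, seed = 109)
  sim <- simulate_reads(ref, cfg)
  corr <- correct_reads(sim$reads, ref)
  expect_true(all(corr$table$functionality_after == "productive"))
  # recovery equals the share that was not productive before
  expect_equal(recovery_rate(corr),
               mean(corr$table$functionality_before != "productive"))
})

test_that("in-frame substitution-only reads escape detection (residual errors)", {
  ref <- tiny_ref()
  cfg <- sim_config(p_accurate = 0, p_single_ins = 0, p_multi_ins = 0,
                    p_single_del = 0, p_single_sub = 1, p_mixed = 0,
                    n_reads = 120, seed = 113)
  sim <- simulate_reads(ref, cfg)
  corr <- correct_reads(sim$reads, ref)
  no_stop <- corr$table$functionality_before != "stop_codon"
  expect_gt(sum(no_stop), 0)
  # undetected: productive before, zero edits, productive after
  expect_true(all(corr$table$functionality_before[no_stop] == "productive"))
  expect_true(all(corr$table$n_edits[no_stop] == 0))
  expect_false(any(corr$table$recovered[no_stop]))
})

test_that("unalignable reads are reported as no_alignment and not corrected", {
  ref <- tiny_ref()
  junk <- paste(rep("ATATATAT", 40), collapse = "")
  res <- correct_read(junk, ref)
  expect_equal(res$functionality_before, "no_alignment")
  expect_false(res$recovered)
  expect_equal(res$uncorrectable_reason, "no_alignment")
  expect_error(recovery_rate(list()), "empty")
})
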