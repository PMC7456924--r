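# Shared fixtures and independent brute-force oracles.

tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# random helical-ish sequence with leucines sprinkled in
random_seq <- function(len, id = "RND", leu_rate = 0.2) {
  pool <- c("A", "E", "K", "Q", "R", "S", "T", "N")
  ch <- sample(pool, len, replace = TRUE)
  ch[stats::runif(len) < leu_rate] <- "L"
  ch[1] <- "M"
  protein_seq(id, paste(ch, collapse = ""))
}

# oracle: zipper score by direct all-pairs distance enumeration on the
# threaded model's anchor coordinates (independent of the scan fast path)
brute_zipper <- function(model, cutoff = 8.0) {
  cbA <- lsukit:::model_anchor_coords(model, "A")
  cbB <- lsukit:::model_anchor_coords(model, "B")
  isLA <- model$chainA$aa == "L"
  isLB <- model$chainB$aa == "L"
  if (!any(isLA) || !any(isLB)) return(0L)
  inA <- logical(sum(isLA)); inB <- logical(sum(isLB))
  ia <- which(isLA); ib <- which(isLB)
  for (i in seq_along(ia)) {
    for (j in seq_along(ib)) {
      d <- sqrt(sum((cbA[ia[i], ] - cbB[ib[j], ])^2))
      if (d <= cutoff + 1e-9) {
        inA[i] <- TRUE
        inB[j] <- TRUE
      }
    }
  }
  sum(inA) + sum(inB)
}

# oracle: exhaustive argmax over the shift grid by threading every model
brute_best_shifts <- function(seqA, seqB, region, template, half_width,
                              cutoff = 8.0) {
  best <- -Inf
  hits <- list()
  for (sA in -half_width:half_width) {
    for (sB in -half_width:half_width) {
      m <- tryCatch(thread_dimer(seqA, seqB, region, template, sA, sB),
                    error = function(e) NULL)
      if (is.null(m)) next
      sc <- brute_zipper(m, cutoff)
      if (sc > best) {
        best <- sc
        hits <- list(c(sA, sB))
      } else if (sc == best) {
        hits[[length(hits) + 1L]] <- c(sA, sB)
      }
    }
  }
  list(score = best, shifts = do.call(rbind, hits))
}

# small TAP-MS fixture: 2 conditions x (1 bait + control), known ratios
toy_tapms <- function() {
  design <- tibble::tibble(
    sample = c("p1", "p2", "c1", "c2"),
    bait = c("LSU1-TAP", "LSU1-TAP", "control-TAP", "control-TAP"),
    condition = "4d_nS",
    replicate = c(1L, 2L, 1L, 2L))
  table <- tibble::tibble(
    id = c("ENRICHED", "FLAT", "ABSENT", "NOCTRL"),
    mw_kda = c(50, 20, 30, 40),
    p1 = c(1e5, 500, 0, 1000),
    p2 = c(1e5, 500, 0, 1000),
    c1 = c(1e3, 500, 800, 0),
    c2 = c(1e3, 500, 800, 0))
  list(table = table, design = design)
}
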