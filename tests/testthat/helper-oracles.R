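# Independent reference implementations used to cross-check the package.
# These are deliberately written from the stated definitions (explicit
# loops, substr-based character access) rather than sharing code with the
# package internals.

# Exhaustive placement search: every (start, loop length) pair, mismatches
# counted position by position at consensus positions, elastic loop
# (surplus residues uncounted), tie-break (total, |loop - mode|, start,
# loop).
brute_locate <- function(sequence, profile, loop_range = c(5L, 15L), loop_mode = 6L) {
  cons <- profile$columns[profile$columns$is_consensus, ]
  b <- profile$region_lengths[["basic"]]
  h1 <- profile$region_lengths[["helix1"]]
  h2 <- profile$region_lengths[["helix2"]]
  cl <- profile$region_lengths[["loop"]]
  n <- nchar(sequence)
  best <- NULL
  for (l in seq.int(loop_range[1], loop_range[2])) {
    D <- b + h1 + l + h2
    if (n < D) next
    for (s in seq_len(n - D + 1)) {
      mm <- c(basic = 0, helix1 = 0, loop = 0, helix2 = 0)
      for (k in seq_len(nrow(cons))) {
        p <- cons$position[k]
        if (p <= b + h1) {
          prot_pos <- s + p - 1
        } else if (p <= b + h1 + cl) {
          j <- p - (b + h1)
          if (j > min(l, cl)) next
          prot_pos <- s + b + h1 + j - 1
        } else {
          h <- p - (b + h1 + cl)
          prot_pos <- s + b + h1 + l + h - 1
        }
        ch <- substr(sequence, prot_pos, prot_pos)
        if (ch != cons$residue[k] || ch == "X" || cons$residue[k] == "X") {
          mm[[cons$region[k]]] <- mm[[cons$region[k]]] + 1
        }
      }
      cand <- list(start = s, loop = l, dev = abs(l - loop_mode),
                   total = sum(mm), mm = mm)
      better <- is.null(best) ||
        cand$total < best$total ||
        (cand$total == best$total && cand$dev < best$dev) ||
        (cand$total == best$total && cand$dev == best$dev && cand$start < best$start) ||
        (cand$total == best$total && cand$dev == best$dev &&
         cand$start == best$start && cand$loop < best$loop)
      if (better) best <- cand
    }
  }
  best
}

# Random protein string over the 20-letter alphabet.
random_protein <- function(n) {
  paste(sample(c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  ), n, replace = TRUE), collapse = "")
}

# A tiny hand-made alignment whose column statistics are computed by eye
# in the tests.
tiny_alignment <- function(rows) {
  tibble::tibble(id = sprintf("s%d", seq_along(rows)), aligned = rows)
}

# One-transcript gene-model feature table built by hand: `pieces` is a
# list of c(exon_start, exon_end, cds_start, cds_end) in genomic
# coordinates.
manual_gene <- function(gene_id, tx_id, chrom, strand, pieces) {
  rows <- lapply(pieces, function(p) {
    tibble::tibble(
      gene_id = gene_id, transcript_id = tx_id, chromosome = chrom,
      strand = strand,
      type = c("exon", "CDS"),
      start = c(p[1], p[3]), end = c(p[2], p[4]),
      frame = c(NA_integer_, 0L)
    )
  })
  out <- dplyr::bind_rows(rows)
  # frames recomputed from transcription-order cumulative CDS length
  cds <- out[out$type == "CDS", ]
  ord <- order(if (strand == "+") cds$start else -cds$start)
  widths <- (cds$end - cds$start + 1)[ord]
  frames <- (3 - (c(0, cumsum(widths))[seq_along(widths)] %% 3)) %% 3
  out$frame[out$type == "CDS"][ord] <- as.integer(frames)
  out
}

# Minimal hits row for a known planted domain.
manual_hit <- function(id, start, loop_length = 6L, domain_length = 54L + loop_length,
                       total = 0, accepted = TRUE) {
  tibble::tibble(
    protein_id = id, start = as.integer(start),
    end = as.integer(start + domain_length - 1L),
    domain_length = as.integer(domain_length),
    loop_length = as.integer(loop_length),
    mm_basic = 0, mm_helix1 = 0, mm_loop = 0, mm_helix2 = 0,
    total_mismatches = total, accepted = accepted
  )
}
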