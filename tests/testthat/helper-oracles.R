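# Independent brute-force oracles used to validate the optimised
# implementations. These deliberately share no code with the package
# internals: plain loops, explicit base tables.

DNA <- c("A", "C", "G", "T")

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA, n, replace = TRUE, prob = p), collapse = "")
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

rc_chars <- function(x) rev(unname(comp_base[strsplit(x, "")[[1]]]))

# --- tag-vs-reference matcher oracle -----------------------------------------
# Enumerates every ungapped placement of the tag against the reference with
# both end offsets bounded by `ov`, counting overlap mismatches by explicit
# loop. Returns NULL or list(mismatches, offset_5p, offset_3p).
oracle_match_tag <- function(tag, ref, mm_max = 2, ov = 2) {
  tc <- strsplit(tag, "")[[1]]
  rc <- strsplit(ref, "")[[1]]
  best <- NULL
  for (p in (1 - ov):(1 + ov)) {  # ref position of tag base 1
    o5 <- 1 - p
    o3 <- (p + length(tc) - 1) - length(rc)
    if (abs(o3) > ov) next
    mism <- 0
    n_overlap <- 0
    for (t in seq_along(tc)) {
      r <- p + t - 1
      if (r >= 1 && r <= length(rc)) {
        n_overlap <- n_overlap + 1
        if (tc[t] != rc[r]) mism <- mism + 1
      }
    }
    if (n_overlap == 0) next
    cand <- list(mismatches = mism, offset_5p = o5, offset_3p = o3)
    if (is.null(best) ||
        mism < best$mismatches ||
        (mism == best$mismatches &&
         abs(o5) + abs(o3) < abs(best$offset_5p) + abs(best$offset_3p))) {
      best <- cand
    }
  }
  if (is.null(best) || best$mismatches > mm_max) return(NULL)
  best
}

# --- genome mapping oracle ---------------------------------------------------
# Sliding-window scan: for every window of width L-1, L, L+1 on either
# strand, evaluates whether the query aligns with <=2 substitutions and <=1
# single-nucleotide gap (deletion anywhere in the query; genomic insertion at
# interior window positions).
oracle_map <- function(query, genome, mm_max = 2) {
  hits <- list()
  L <- nchar(query)
  hamming <- function(a, b) sum(a != b)
  for (ci in seq_along(genome)) {
    gchars <- strsplit(genome[[ci]], "")[[1]]
    n <- length(gchars)
    for (strand in c("+", "-")) {
      qc <- if (strand == "+") strsplit(query, "")[[1]] else rc_chars(query)
      for (w in c(L - 1, L, L + 1)) {
        if (w > n) next
        for (i in 1:(n - w + 1)) {
          win <- gchars[i:(i + w - 1)]
          res <- NULL
          if (w == L) {
            d <- hamming(qc, win)
            if (d <= mm_max) res <- c(d, 0)
          } else if (w == L - 1) {
            best <- Inf
            for (j in 1:L) {
              d <- hamming(qc[-j], win)
              if (d < best) best <- d
            }
            if (best <= mm_max) res <- c(best, 1)
          } else {
            best <- Inf
            for (k in 2:(w - 1)) {
              d <- hamming(qc, win[-k])
              if (d < best) best <- d
            }
            if (best <= mm_max) res <- c(best, 1)
          }
          if (!is.null(res)) {
            hits[[length(hits) + 1]] <- data.frame(
              contig = names(genome)[ci], start0 = i - 1, end0 = i - 1 + w,
              strand = strand, mismatches = res[1], gaps = res[2]
            )
          }
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(contig = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      mismatches = integer(), gaps = integer()))
  }
  out <- do.call(rbind, hits)
  # keep the best (fewest gaps then mismatches) interpretation per window
  out <- out[order(out$contig, out$start0, out$end0, out$strand,
                   out$gaps, out$mismatches), ]
  out[!duplicated(out[, c("contig", "start0", "end0", "strand")]), ]
}

# --- target duplex oracle ----------------------------------------------------
# Penalty for one aligned column: m = miRNA base, t = target base.
oracle_col_pen <- function(m, t) {
  if (comp_base[[m]] == t) return(0)
  if ((m == "G" && t == "T") || (m == "T" && t == "G")) return(0.5)
  1
}

# Expectation of one window under a fixed gap layout. `layout` is a data
# frame of columns with mirna_pos (NA = target bulge) and win_pos (NA =
# miRNA bulge).
oracle_layout_score <- function(layout, mc, win, seed_lo = 2, seed_hi = 13) {
  tot <- 0
  seed_mm <- 0
  for (r in seq_len(nrow(layout))) {
    mp <- layout$mirna_pos[r]
    wp <- layout$win_pos[r]
    pos <- if (is.na(mp)) layout$anchor_pos[r] else mp
    mult <- if (pos >= seed_lo && pos <= seed_hi) 2 else 1
    if (is.na(mp) || is.na(wp)) {
      tot <- tot + 2 * mult
      if (pos >= seed_lo && pos <= seed_hi) seed_mm <- seed_mm + 1
    } else {
      pen <- oracle_col_pen(mc[mp], win[wp])
      tot <- tot + pen * mult
      if (pen == 1 && pos >= seed_lo && pos <= seed_hi) seed_mm <- seed_mm + 1
    }
  }
  list(expectation = tot, seed_mismatches = seed_mm)
}

# All gap layouts for a miRNA of length L against a window of width w.
# miRNA position L pairs the first window base (target read 3'->5').
oracle_layouts <- function(L, w) {
  layouts <- list()
  if (w == L) {
    layouts[[1]] <- data.frame(mirna_pos = L:1, win_pos = 1:L,
                               anchor_pos = L:1)
  } else if (w > L && w - L <= 2) {
    g <- w - L
    for (j in 2:L) {  # bulge sits between miRNA positions; anchor at pos j'
      pre <- data.frame(mirna_pos = L:(L - j + 2), win_pos = 1:(j - 1),
                        anchor_pos = L:(L - j + 2))
      bulge <- data.frame(mirna_pos = NA, win_pos = j:(j + g - 1),
                          anchor_pos = L + 1 - j)
      post <- data.frame(mirna_pos = (L - j + 1):1, win_pos = (j + g):w,
                         anchor_pos = (L - j + 1):1)
      layouts[[length(layouts) + 1]] <- rbind(pre, bulge, post)
    }
  } else if (w < L && L - w <= 2) {
    g <- L - w
    for (j in 2:(L - g)) {  # miRNA positions unpaired (oracle indexes from 3')
      pre <- data.frame(mirna_pos = L:(L - j + 2), win_pos = 1:(j - 1),
                        anchor_pos = L:(L - j + 2))
      bulge <- data.frame(mirna_pos = (L - j + 1):(L - j - g + 2), win_pos = NA,
                          anchor_pos = (L - j + 1):(L - j - g + 2))
      post <- data.frame(mirna_pos = (L - j - g + 1):1, win_pos = j:w,
                         anchor_pos = (L - j - g + 1):1)
      layouts[[length(layouts) + 1]] <- rbind(pre, bulge, post)
    }
  }
  layouts
}

# Best expectation and seed mismatches at every window of a transcript.
oracle_scan <- function(mirna, transcript, cutoff = 5, max_seed_mm = 2) {
  mc <- strsplit(mirna, "")[[1]]
  tc <- strsplit(transcript, "")[[1]]
  L <- length(mc)
  hits <- list()
  for (w in (L - 2):(L + 2)) {
    if (w < 1 || w > length(tc)) next
    layouts <- oracle_layouts(L, w)
    for (s in 1:(length(tc) - w + 1)) {
      win <- tc[s:(s + w - 1)]
      for (lay in layouts) {
        sc <- oracle_layout_score(lay, mc, win)
        if (sc$expectation <= cutoff && sc$seed_mismatches <= max_seed_mm) {
          hits[[length(hits) + 1]] <- data.frame(
            target_start = s, target_end = s + w - 1,
            expectation = sc$expectation,
            seed_mismatches = sc$seed_mismatches
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(target_start = integer(), target_end = integer(),
                      expectation = numeric(), seed_mismatches = integer()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$target_start, out$target_end, out$expectation), ]
  out[!duplicated(out[, c("target_start", "target_end")]), ]
}

# --- Benjamini-Hochberg step-up oracle --------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
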