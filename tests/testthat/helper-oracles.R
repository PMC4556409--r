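# Independent brute-force reference implementations. These are deliberately
# naive (explicit loops, per-base arithmetic) and share no code with the
# package internals they check.

oracle_peak_normalize <- function(cov, window = 1000, q = 95, red = 0.10) {
  out <- cov[order(cov$scaffold, cov$pos), ]
  i <- 1
  n <- nrow(out)
  while (i <= n) {
    # find the end of the contiguous track starting at i
    j <- i
    while (j < n && out$scaffold[j + 1] == out$scaffold[j] &&
           out$pos[j + 1] == out$pos[j] + 1) {
      j <- j + 1
    }
    k <- i
    while (k <= j) {
      kk <- min(k + window - 1, j)
      w <- out$depth[k:kk]
      p <- sort(w)[max(1, ceiling(q / 100 * length(w)))]
      for (m in k:kk) {
        out$depth[m] <- max(0, out$depth[m] - red * p)
      }
      k <- kk + 1
    }
    i <- j + 1
  }
  out
}

oracle_filter_introns <- function(hints, thr = 0.90) {
  h <- hints
  ord <- order(-h$multiplicity, h$scaffold, h$start, h$end)
  alive <- rep(TRUE, nrow(h))
  for (j in ord) {
    for (k in seq_len(nrow(h))) {
      if (k == j || !alive[k]) next
      if (h$scaffold[k] != h$scaffold[j]) next
      if (h$multiplicity[k] < h$multiplicity[j]) next
      if (h$start[k] >= h$end[j] || h$end[k] <= h$start[j]) next
      if ((h$multiplicity[k] - h$multiplicity[j]) / h$multiplicity[k] >
          thr) {
        alive[j] <- FALSE
        break
      }
    }
  }
  h[alive, , drop = FALSE]
}

oracle_attenuate <- function(cov, hints, max_intron = 50000, flank = 10,
                             drop = 0.5, att = 0.5) {
  out <- cov
  snapshot <- new.env(hash = TRUE)
  for (i in seq_len(nrow(cov))) {
    assign(paste0(cov$scaffold[i], ":", cov$pos[i]), cov$depth[i],
           envir = snapshot)
  }
  depth0 <- function(scaf, p) {
    key <- paste0(scaf, ":", p)
    if (exists(key, envir = snapshot, inherits = FALSE)) {
      get(key, envir = snapshot)
    } else 0
  }
  mean0 <- function(scaf, from, to) {
    v <- numeric(0)
    for (p in from:(to - 1)) v <- c(v, depth0(scaf, p))
    mean(v)
  }
  for (i in seq_len(nrow(hints))) {
    h <- hints[i, ]
    if (h$end - h$start > max_intron) next
    ex_l <- mean0(h$scaffold, h$start - flank, h$start)
    in_l <- mean0(h$scaffold, h$start, h$start + flank)
    in_r <- mean0(h$scaffold, h$end - flank, h$end)
    ex_r <- mean0(h$scaffold, h$end, h$end + flank)
    if (!(in_l <= (1 - drop) * ex_l && in_r <= (1 - drop) * ex_r)) next
    e <- (ex_l + ex_r) / 2
    sel <- out$scaffold == h$scaffold & out$pos >= h$start &
      out$pos < h$end
    out$depth[sel] <- pmax(0, out$depth[sel] - att * e)
  }
  out
}

oracle_rbh <- function(ab, ba, evalue_max = 1e-5, len_frac = 0.5) {
  keep <- function(h) {
    h[h$evalue <= evalue_max & h$alignment_length >= len_frac * h$qlen, ,
      drop = FALSE]
  }
  best_of <- function(h, q) {
    hh <- h[h$query == q, , drop = FALSE]
    if (!nrow(hh)) return(NA_character_)
    hh <- hh[order(-hh$bitscore, hh$evalue, hh$subject), , drop = FALSE]
    hh$subject[1]
  }
  ab <- keep(ab); ba <- keep(ba)
  pairs <- list()
  for (a in unique(ab$query)) {
    b <- best_of(ab, a)
    if (is.na(b)) next
    if (identical(best_of(ba, b), a)) {
      pairs[[length(pairs) + 1]] <- data.frame(a = a, b = b)
    }
  }
  if (!length(pairs)) return(data.frame(a = character(), b = character()))
  p <- do.call(rbind, pairs)
  p[order(p$a), , drop = FALSE]
}

# brute-force stable-id assignment via per-base position sets
oracle_transfer <- function(old_aln, new_genes) {
  base_set <- function(scaf, s, e) paste0(scaf, ":", unlist(mapply(
    function(a, b) a:(b - 1), s, e, SIMPLIFY = FALSE)))
  old_ids <- unique(old_aln$old_id)
  old_sets <- lapply(old_ids, function(id) {
    b <- old_aln[old_aln$old_id == id, ]
    base_set(b$scaffold[1], b$start, b$end)
  })
  names(old_sets) <- old_ids
  new_ids <- unique(new_genes$gene_id)
  new_sets <- lapply(new_ids, function(id) {
    ex <- new_genes[new_genes$gene_id == id, ]
    cs <- pmax(ex$start, ex$cds_start); ce <- pmin(ex$end, ex$cds_end)
    ok <- cs < ce
    if (!any(ok)) return(character())
    base_set(ex$scaffold[1], cs[ok], ce[ok])
  })
  names(new_sets) <- new_ids
  ov <- matrix(0, length(old_ids), length(new_ids),
               dimnames = list(old_ids, new_ids))
  for (o in old_ids) for (n in new_ids) {
    ov[o, n] <- length(intersect(old_sets[[o]], new_sets[[n]]))
  }
  new_start <- sapply(new_ids, function(id) {
    min(new_genes$start[new_genes$gene_id == id])
  })
  best <- list()
  for (o in old_ids) {
    if (max(ov[o, ]) == 0) next
    cand <- new_ids[ov[o, ] == max(ov[o, ])]
    cand <- cand[order(new_start[cand], cand)]
    best[[o]] <- cand[1]
  }
  # reciprocal resolution per new gene: largest overlap wins
  assign <- list()
  for (n in unique(unlist(best))) {
    olds <- names(best)[vapply(best, identical, TRUE, y = n)]
    w <- olds[order(-ov[olds, n])][1]
    assign[[n]] <- w
  }
  data.frame(new_id = names(assign), old_id = unlist(assign),
             row.names = NULL)
}

oracle_find_orf <- function(s, min_codons) {
  s <- toupper(s)
  n <- nchar(s)
  best <- NULL
  for (st in seq_len(max(0, n - 5)) - 1L) {  # 0-based candidate starts
    if (substr(s, st + 1, st + 3) != "ATG") next
    p <- st
    repeat {
      if (p + 3 > n) break
      cod <- substr(s, p + 1, p + 3)
      if (p > st && cod %in% c("TAA", "TAG", "TGA")) {
        aa <- (p - st) / 3
        if (aa >= min_codons &&
            (is.null(best) || aa > best$aa)) {
          best <- list(start = st, end = p + 3, aa = aa)
        }
        break
      }
      p <- p + 3
    }
  }
  best
}

# brute-force sensitivity/precision via string sets
oracle_eval <- function(pred, ref) {
  exset <- function(g) unique(paste(g$scaffold, g$strand, g$start, g$end))
  txset <- function(g) {
    sapply(split(g[order(g$start), ], g$transcript_id[order(g$start)]),
           function(t) paste(t$scaffold[1], t$strand[1],
                             paste(t$start, t$end, collapse = " ")))
  }
  pe <- exset(pred); re <- exset(ref)
  pt <- txset(pred); rt <- txset(ref)
  list(exon_sn = length(intersect(pe, re)) / length(re),
       exon_sp = length(intersect(pe, re)) / length(pe),
       tx_sn = sum(pt %in% rt) / length(rt),
       tx_sp = sum(pt %in% rt) / length(pt))
}
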