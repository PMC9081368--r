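# Independent naive reference implementations of every descriptor, used to
# cross-check the package encoders. Deliberately written as plain
# character-by-character loops with no code shared with the package
# internals (only the shipped property tables are reused — they are data).

rand_seq <- function(L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               L, replace = TRUE), collapse = "")
}

AA_ABC <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

oracle_aac <- function(s) {
  ch <- chars_of(s)
  out <- numeric(20)
  for (i in seq_along(AA_ABC)) {
    n <- 0
    for (c in ch) if (c == AA_ABC[i]) n <- n + 1
    out[i] <- n / length(ch)
  }
  out
}

oracle_188d <- function(s, tables = mhcvote::aa_property_tables()) {
  ch <- chars_of(s)
  L <- length(ch)
  out <- oracle_aac(s)
  for (prop in names(tables$ctd)) {
    cls <- as.integer(tables$ctd[[prop]][ch])
    # composition
    for (k in 1:3) out <- c(out, sum(cls == k) / L)
    # transition over unordered class pairs
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      n <- 0
      if (L > 1) {
        for (i in 1:(L - 1)) {
          if ((cls[i] == p[1] && cls[i + 1] == p[2]) ||
              (cls[i] == p[2] && cls[i + 1] == p[1])) n <- n + 1
        }
      }
      out <- c(out, if (L > 1) n / (L - 1) else 0)
    }
    # distribution: first / 25% / 50% / 75% / last occurrence as % of L
    for (k in 1:3) {
      pos <- which(cls == k)
      if (length(pos) == 0) {
        out <- c(out, rep(0, 5))
      } else {
        n <- length(pos)
        picks <- c(1, ceiling(0.25 * n), ceiling(0.5 * n), ceiling(0.75 * n), n)
        out <- c(out, pos[picks] / L * 100)
      }
    }
  }
  out
}

oracle_apaac <- function(s, lambda, w, tables = mhcvote::aa_property_tables()) {
  ch <- chars_of(s)
  L <- length(ch)
  h1 <- tables$scales$h1
  h2 <- tables$scales$h2
  tau <- numeric(0)
  for (j in 1:lambda) {
    t1 <- 0
    t2 <- 0
    for (i in 1:(L - j)) {
      t1 <- t1 + h1[[ch[i]]] * h1[[ch[i + j]]]
      t2 <- t2 + h2[[ch[i]]] * h2[[ch[i + j]]]
    }
    tau <- c(tau, t1 / (L - j), t2 / (L - j))
  }
  f <- oracle_aac(s)
  denom <- sum(f) + w * sum(tau)
  c(f, w * tau) / denom
}

oracle_paac <- function(s, lambda, w, tables = mhcvote::aa_property_tables()) {
  ch <- chars_of(s)
  L <- length(ch)
  sc <- tables$scales
  theta <- numeric(0)
  for (j in 1:lambda) {
    acc <- 0
    for (i in 1:(L - j)) {
      a <- ch[i]
      b <- ch[i + j]
      acc <- acc + ((sc$h1[[b]] - sc$h1[[a]])^2 +
                    (sc$h2[[b]] - sc$h2[[a]])^2 +
                    (sc$m[[b]] - sc$m[[a]])^2) / 3
    }
    theta <- c(theta, acc / (L - j))
  }
  f <- oracle_aac(s)
  denom <- sum(f) + w * sum(theta)
  c(f, w * theta) / denom
}

oracle_ksctriad <- function(s, kmax, norm = "minmax",
                            tables = mhcvote::aa_property_tables()) {
  ch <- chars_of(s)
  L <- length(ch)
  tri <- as.integer(tables$triad[ch])
  out <- numeric(0)
  for (k in 0:kmax) {
    g <- k + 1
    counts <- numeric(343)
    cell <- 0
    for (c1 in 1:7) for (c2 in 1:7) for (c3 in 1:7) {
      cell <- cell + 1
      n <- 0
      i <- 1
      while (i + 2 * g <= L) {
        if (tri[i] == c1 && tri[i + g] == c2 && tri[i + 2 * g] == c3) n <- n + 1
        i <- i + 1
      }
      counts[cell] <- n
    }
    if (norm == "minmax") {
      if (max(counts) > 0) {
        counts <- (counts - min(counts)) / max(counts)
      }
    } else {
      counts <- counts / (L - 2 * g)
    }
    out <- c(out, counts)
  }
  out
}

oracle_pairs <- function(s, kmax, classes, n_classes) {
  ch <- chars_of(s)
  L <- length(ch)
  cls <- as.integer(classes[ch])
  out <- numeric(0)
  for (k in 0:kmax) {
    counts <- numeric(n_classes^2)
    cell <- 0
    for (a in 1:n_classes) for (b in 1:n_classes) {
      cell <- cell + 1
      n <- 0
      for (i in 1:(L - k - 1)) {
        if (cls[i] == a && cls[i + k + 1] == b) n <- n + 1
      }
      counts[cell] <- n
    }
    out <- c(out, counts / (L - k - 1))
  }
  out
}

oracle_cksaagp <- function(s, kmax, tables = mhcvote::aa_property_tables()) {
  oracle_pairs(s, kmax, tables$group, 5)
}

oracle_cksaap <- function(s, kmax) {
  codes <- stats::setNames(1:20, AA_ABC)
  oracle_pairs(s, kmax, codes, 20)
}

# small labeled dataset written to FASTA pair; returns the two paths
write_fasta_pair <- function(ds, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  pos <- file.path(dir, "pos.fasta")
  neg <- file.path(dir, "neg.fasta")
  mhcvote::write_fasta(ds[ds$label == 1L, ], pos)
  mhcvote::write_fasta(ds[ds$label == 0L, ], neg)
  list(pos = pos, neg = neg)
}
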