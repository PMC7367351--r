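# shared fixtures and independent oracles for the test suite

# edits on the demo target (cut site 0-based 90, 1-based 91)
demo_edits <- function() {
  list(
    syn = data.frame(pos = 96, ref = "A", alt = "G"),   # GAA->GAG, synonymous
    mis = data.frame(pos = 96, ref = "A", alt = "C"),   # GAA->GAC, missense
    del2 = data.frame(pos = 89, ref = "CTG", alt = "C"), # 2-bp frameshift deletion
    del3 = data.frame(pos = 89, ref = "CTGT", alt = "C"), # 3-bp in-frame deletion
    ins2 = data.frame(pos = 91, ref = "G", alt = "GAT"), # 2-bp frameshift insertion
    snv = data.frame(pos = 85, ref = "A", alt = "C")     # missense SNV 6 bp away
  )
}

variant_key <- function(v) {
  if (is.null(v) || nrow(v) == 0) return("")
  paste(sprintf("%d:%s>%s", v$pos, v$ref, v$alt), collapse = ";")
}

called_genotype <- function(sc) {
  if (sc$status != "called") return(c("?", "?"))
  sort(vapply(sc$alleles, function(a) variant_key(a$variants), ""))
}

# independent alignment-score oracle: top-down recursion over
# (read consumed, ref consumed, op to the right), memoised. A gap run of
# length L costs open + (L-1)*ext regardless of traversal direction.
oracle_align_score <- function(read, ref, match = 2, mismatch = -3,
                               open = -6, ext = -1) {
  r <- strsplit(read, "")[[1]]; f <- strsplit(ref, "")[[1]]
  memo <- new.env(hash = TRUE)
  best <- function(i, j, last) {
    if (i == 0 && j == 0) return(0)
    key <- paste(i, j, last)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    cand <- -Inf
    if (i > 0 && j > 0) {
      s <- if (r[i] == f[j] && r[i] != "N") match else mismatch
      cand <- max(cand, best(i - 1, j - 1, "M") + s)
    }
    if (j > 0) cand <- max(cand, best(i, j - 1, "D") + if (last == "D") ext else open)
    if (i > 0) cand <- max(cand, best(i - 1, j, "I") + if (last == "I") ext else open)
    memo[[key]] <- cand
    cand
  }
  best(length(r), length(f), "start")
}

# brute-force enumeration of every alignment path (no memoisation, no DP):
# validates the memoised oracle on tiny inputs
enumerate_align_score <- function(read, ref, match = 2, mismatch = -3,
                                  open = -6, ext = -1) {
  r <- strsplit(read, "")[[1]]; f <- strsplit(ref, "")[[1]]
  best <- -Inf
  walk <- function(i, j, last, acc) {
    if (i == 0 && j == 0) { best <<- max(best, acc); return(invisible()) }
    if (i > 0 && j > 0) {
      s <- if (r[i] == f[j] && r[i] != "N") match else mismatch
      walk(i - 1, j - 1, "M", acc + s)
    }
    if (j > 0) walk(i, j - 1, "D", acc + if (last == "D") ext else open)
    if (i > 0) walk(i - 1, j, "I", acc + if (last == "I") ext else open)
  }
  walk(length(r), length(f), "start", 0)
  best
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# population SD, the convention used for SDNN
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
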