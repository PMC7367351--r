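#' Define an amplicon target
#'
#' @param name Gene/site label.
#' @param reference Wildtype amplicon DNA sequence (ACGT, 100-400 bp).
#' @param cut_site 0-based reference offset of the Cas9 cut site.
#' @param cds_frame_offset 0, 1 or 2: codon position of reference base 0
#'   (after reverse-complementing when `strand == "-"`).
#' @param strand `"+"` or `"-"`.
#' @param blacklist data.frame of naturally occurring variants to exclude
#'   (`pos` 1-based anchor, `ref`, `alt`), or NULL.
#' @return Object of class `amplicon_target`.
#' @export
amplicon_target <- function(name, reference, cut_site, cds_frame_offset = 0L,
                            strand = "+", blacklist = NULL) {
  reference <- toupper(reference)
  stopifnot(nchar(reference) >= 100, nchar(reference) <= 400,
            grepl("^[ACGT]+$", reference),
            cut_site >= 0, cut_site < nchar(reference),
            cds_frame_offset %in% 0:2, strand %in% c("+", "-"))
  if (!is.null(blacklist) && nrow(blacklist)) {
    stopifnot(all(c("pos", "ref", "alt") %in% names(blacklist)))
    if (any(blacklist$pos < 1 | blacklist$pos > nchar(reference)))
      stop("blacklist position outside the reference")
  } else blacklist <- data.frame(pos = integer(0), ref = character(0),
                                 alt = character(0), stringsAsFactors = FALSE)
  structure(list(name = name, reference = reference,
                 cut_site = as.integer(cut_site),
                 cds_frame_offset = as.integer(cds_frame_offset),
                 strand = strand, blacklist = blacklist),
            class = "amplicon_target")
}

#' @export
print.amplicon_target <- function(x, ...) {
  cat("amplicon_target", x$name, ":", nchar(x$reference), "bp, cut site",
      x$cut_site, "(0-based), strand", x$strand, ",",
      nrow(x$blacklist), "blacklisted variant(s)\n")
  invisible(x)
}

#' A small built-in demonstration target
#'
#' A fixed 180-bp synthetic coding amplicon (frame offset 0, + strand) with
#' the cut site at 0-based position 90. The codon spanning 1-based
#' positions 94-96 is GAA (Glu), so a substitution at position 96 (5 bp
#' from the cut site) is synonymous for A->G and missense for A->C.
#'
#' @return An `amplicon_target`.
#' @export
demo_target <- function() {
  amplicon_target(
    name = "demo1",
    reference = paste0(
      "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGA",
      "ACCCCCTGCACGCCCTAAAGTACAATTACTGTAGAAATCCCTACACTGTATATGCCGAAC",
      "GTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCT"),
    cut_site = 90L, cds_frame_offset = 0L, strand = "+")
}

#' Globally align a read to the amplicon reference
#'
#' Optimal global alignment under affine-gap scoring (match +2, mismatch
#' -3, gap open -6 for the first gapped base, -1 per additional base) via
#' a Gotoh dynamic program. `N` bases match nothing and score as
#' mismatches. Tie-breaks are deterministic: match/mismatch preferred over
#' gaps, deletion over insertion, and equivalent gaps placed leftmost.
#' Reads scoring below `-0.5 * read length` are rejected as unmappable.
#'
#' @param read Read sequence (ACGTN, non-empty).
#' @param target An [amplicon_target()].
#' @param read_id Identifier carried into the result.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return Object of class `read_alignment`: list with `read_id`, `score`,
#'   `ops` (per-column string over `=`, `X`, `I`, `D`), `cigar`
#'   (run-length form), `start`, `end` (0-based half-open on the
#'   reference), `mappable`.
#' @export
align_read <- function(read, target, read_id = "read",
                       match = 2, mismatch = -3, gap_open = -6, gap_extend = -1) {
  read <- toupper(read)
  if (!nzchar(read)) stop("empty read")
  if (!grepl("^[ACGTN]+$", read)) stop("read contains non-ACGTN characters")
  res <- gotoh_align(read, target$reference, match, mismatch, gap_open, gap_extend)
  ops <- res$ops
  r <- rle(strsplit(ops, "")[[1]])
  cigar <- paste0(r$lengths, r$values, collapse = "")
  structure(list(read_id = read_id, score = res$score, ops = ops,
                 cigar = cigar, start = 0L, end = nchar(target$reference),
                 mappable = res$score >= -0.5 * nchar(read)),
            class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cat("read_alignment", x$read_id, ": score", x$score, ",", x$cigar, "\n")
  invisible(x)
}

# left-normalize an indel (VCF anchor-base convention).
# pos: 1-based anchor; for deletions `seq` = deleted bases, for insertions
# `seq` = inserted bases placed after the anchor.
left_normalize <- function(reference, pos, seq, kind) {
  L <- nchar(seq)
  refc <- strsplit(reference, "")[[1]]
  sq <- strsplit(seq, "")[[1]]
  if (kind == "deletion") {
    # deleted run occupies reference positions (pos+1)..(pos+L)
    while (pos >= 1 && pos + L <= length(refc) && refc[pos + L] == refc[pos]) {
      pos <- pos - 1
    }
    if (pos < 1) pos <- 1 else sq <- refc[(pos + 1):(pos + L)]
    sq <- refc[(pos + 1):(pos + L)]
  } else {
    while (pos >= 1 && sq[L] == refc[pos]) {
      sq <- c(refc[pos], sq[-L])
      pos <- pos - 1
    }
    if (pos < 1) pos <- 1
  }
  list(pos = pos, seq = paste(sq, collapse = ""))
}

# extract raw variants (1-based, VCF anchor convention) from alignment ops
variants_from_ops <- function(read, ops, target) {
  refc <- strsplit(target$reference, "")[[1]]
  readc <- strsplit(read, "")[[1]]
  opc <- strsplit(ops, "")[[1]]
  out <- list()
  i <- 0L; j <- 0L  # read / reference cursors (consumed counts)
  k <- 1L
  n_ops <- length(opc)
  while (k <= n_ops) {
    op <- opc[k]
    run <- 1L
    while (k + run <= n_ops && opc[k + run] == op) run <- run + 1L
    if (op == "=" ) { i <- i + run; j <- j + run }
    else if (op == "X") {
      for (t in seq_len(run)) {
        out[[length(out) + 1]] <- list(pos = j + t, ref = refc[j + t],
                                       alt = readc[i + t], kind = "snv")
      }
      i <- i + run; j <- j + run
    } else if (op == "D") {
      del <- paste(refc[(j + 1):(j + run)], collapse = "")
      nl <- left_normalize(target$reference, j, del, "deletion")
      anchor <- max(nl$pos, 1)
      out[[length(out) + 1]] <- list(
        pos = anchor,
        ref = paste0(refc[anchor], nl$seq),
        alt = refc[anchor], kind = "deletion")
      j <- j + run
    } else if (op == "I") {
      ins <- paste(readc[(i + 1):(i + run)], collapse = "")
      nl <- left_normalize(target$reference, j, ins, "insertion")
      anchor <- max(nl$pos, 1)
      out[[length(out) + 1]] <- list(
        pos = anchor,
        ref = refc[anchor],
        alt = paste0(refc[anchor], nl$seq), kind = "insertion")
      i <- i + run
    }
    k <- k + run
  }
  if (!length(out)) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      kind = character(0), cut_distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  df$cut_distance <- vapply(seq_len(nrow(df)), function(r)
    variant_cut_distance(df$pos[r], df$ref[r], df$alt[r], df$kind[r],
                         target$cut_site), numeric(1))
  df <- df[order(df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# min distance (bp) from any affected base to the 0-based cut site
variant_cut_distance <- function(pos, ref, alt, kind, cut_site) {
  cut1 <- cut_site + 1  # 1-based
  if (kind == "snv") return(abs(pos - cut1))
  if (kind == "deletion") {
    affected <- (pos + 1):(pos + nchar(ref) - 1)  # deleted reference bases
  } else {
    affected <- c(pos, pos + 1)  # insertion sits between anchor and next base
  }
  min(abs(affected - cut1))
}

#' Cluster aligned reads into at most two allele haplotypes
#'
#' Reads are grouped by their implied haplotype over the +/- `cut_window`
#' bp cut-site window (i.e. by the set of called variants whose nearest
#' affected base lies within the window). Groups are ranked by read
#' support; groups supported by at least
#' `max(min_support_reads, min_support_fraction * total)` reads survive.
#' One surviving group is a homozygous call (recorded as two identical
#' alleles); two are a heterozygous call; more than two yield a missing
#' call (`"ambiguous"`), none a missing call (`"low support"`).
#'
#' @param read_variants List, one element per mappable read, each a
#'   data.frame of variants as returned by the internal extractor
#'   (columns `pos`, `ref`, `alt`, `kind`, `cut_distance`).
#' @param target An [amplicon_target()].
#' @param min_support_fraction,min_support_reads Support thresholds.
#' @param cut_window Window half-width in bp (default 30).
#' @return List with `status` (`"called"`/`"missing"`), `reason`, and
#'   `alleles`: a list of up to two elements, each with `variants`
#'   (window-restricted variant data.frame), `support`, `haplotype`.
#' @export
cluster_haplotypes <- function(read_variants, target,
                               min_support_fraction = 0.10,
                               min_support_reads = 5L,
                               cut_window = .bc_defaults$cut_window_bp) {
  total <- length(read_variants)
  if (total < 1) return(list(status = "missing", reason = "low support",
                             alleles = list()))
  keys <- vapply(read_variants, function(v) {
    v <- v[v$cut_distance <= cut_window, , drop = FALSE]
    if (!nrow(v)) return("")
    paste(sprintf("%d:%s>%s", v$pos, v$ref, v$alt), collapse = ";")
  }, "")
  tab <- sort(table(keys), decreasing = TRUE)
  thr <- max(min_support_reads, min_support_fraction * total)
  passing <- tab[tab >= thr]
  if (length(passing) == 0)
    return(list(status = "missing", reason = "low support", alleles = list()))
  if (length(passing) > 2)
    return(list(status = "missing", reason = "ambiguous", alleles = list()))
  mk_allele <- function(key, support) {
    idx <- which(keys == key)[1]
    v <- read_variants[[idx]]
    v <- v[v$cut_distance <= cut_window, , drop = FALSE]
    rownames(v) <- NULL
    hap <- apply_variants(target$reference,
                          v[v$kind != "none", c("pos", "ref", "alt")])
    list(variants = v, support = as.integer(support), haplotype = hap)
  }
  alleles <- lapply(seq_along(passing), function(i)
    mk_allele(names(passing)[i], passing[[i]]))
  if (length(alleles) == 1) alleles <- c(alleles, alleles)  # homozygous
  list(status = "called", reason = NA_character_, alleles = alleles)
}

#' Call variants for one allele haplotype
#'
#' Returns the allele's left-normalised variants whose nearest affected
#' base lies within +/- `cut_window` bp of the cut site, with naturally
#' occurring (blacklisted) variants removed.
#'
#' @param allele One element of `cluster_haplotypes()$alleles`.
#' @param target An [amplicon_target()].
#' @param cut_window Window half-width in bp (default 30).
#' @return data.frame with columns `pos`, `ref`, `alt`, `kind`,
#'   `cut_distance`.
#' @export
call_variants <- function(allele, target,
                          cut_window = .bc_defaults$cut_window_bp) {
  v <- allele$variants
  v <- v[v$cut_distance <= cut_window, , drop = FALSE]
  if (nrow(v) && nrow(target$blacklist)) {
    bl <- sprintf("%d:%s>%s", target$blacklist$pos, target$blacklist$ref,
                  target$blacklist$alt)
    v <- v[!(sprintf("%d:%s>%s", v$pos, v$ref, v$alt) %in% bl), , drop = FALSE]
  }
  rownames(v) <- NULL
  v
}

# reverse complement (base R, ACGTN)
revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

#' Annotate the coding consequence of a variant
#'
#' Indels whose length change is not a multiple of 3 are frameshift (HIGH);
#' multiples of 3 are in-frame indels (MODERATE). SNVs are translated in
#' the target's reading frame (on the reverse-complemented sequence for
#' minus-strand targets): a gained stop is `stop_gained` (HIGH), a lost
#' stop `stop_lost` (HIGH), an amino-acid change `missense` (MODERATE) and
#' a silent change `synonymous` (LOW). Variants whose codon is incomplete
#' at the amplicon edge are `noncoding` (MODIFIER). Impact maps to weight
#' via HIGH = 1, MODERATE = 0.66, LOW = 0.33, MODIFIER = 0.
#'
#' @param variant One row of a [call_variants()] data.frame (or a list with
#'   `pos`, `ref`, `alt`, `kind`).
#' @param target An [amplicon_target()].
#' @return List with `category`, `impact`, `weight`.
#' @export
annotate_consequence <- function(variant, target) {
  weights <- .bc_defaults$impact_weights
  len_change <- nchar(variant$alt) - nchar(variant$ref)
  if (variant$kind %in% c("insertion", "deletion") || len_change != 0) {
    if (abs(len_change) %% 3 != 0)
      return(list(category = "frameshift", impact = "HIGH",
                  weight = unname(weights["HIGH"])))
    return(list(category = "inframe_indel", impact = "MODERATE",
                weight = unname(weights["MODERATE"])))
  }
  # SNV: translate the affected codon in the annotated frame
  refseq <- target$reference
  pos0 <- variant$pos - 1L      # 0-based
  alt <- variant$alt
  if (target$strand == "-") {
    refseq <- revcomp(refseq)
    pos0 <- nchar(target$reference) - 1L - pos0
    alt <- chartr("ACGTN", "TGCAN", variant$alt)
  }
  f <- target$cds_frame_offset
  codon_pos <- (pos0 + f) %% 3
  codon_start0 <- pos0 - codon_pos
  if (codon_start0 < 0 || codon_start0 + 2 >= nchar(refseq))
    return(list(category = "noncoding", impact = "MODIFIER",
                weight = unname(weights["MODIFIER"])))
  codon_ref <- substr(refseq, codon_start0 + 1, codon_start0 + 3)
  codon_alt <- codon_ref
  substr(codon_alt, codon_pos + 1, codon_pos + 1) <- alt
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[codon_ref]); aa_alt <- unname(gc[codon_alt])
  if (is.na(aa_ref) || is.na(aa_alt))
    return(list(category = "noncoding", impact = "MODIFIER",
                weight = unname(weights["MODIFIER"])))
  if (aa_alt == aa_ref)
    list(category = "synonymous", impact = "LOW", weight = unname(weights["LOW"]))
  else if (aa_alt == "*")
    list(category = "stop_gained", impact = "HIGH", weight = unname(weights["HIGH"]))
  else if (aa_ref == "*")
    list(category = "stop_lost", impact = "HIGH", weight = unname(weights["HIGH"]))
  else
    list(category = "missense", impact = "MODERATE",
         weight = unname(weights["MODERATE"]))
}

#' Impact-weighted dosage of a site call
#'
#' Per allele, the weight is the maximum of its variants' impact weights
#' (0 for a wildtype allele); the dosage is the sum over the two alleles,
#' in `[0, 2]`.
#'
#' @param call A `site_call` (see [call_site()]).
#' @return Numeric dosage, or `NA` for missing calls.
#' @export
site_dosage <- function(call) {
  if (call$status != "called") return(NA_real_)
  sum(vapply(call$alleles, function(a) {
    if (!nrow(a$variants)) return(0)
    max(vapply(seq_len(nrow(a$variants)), function(i)
      a$variants$weight[i], numeric(1)))
  }, numeric(1)))
}

#' Call a target site for one embryo from its amplicon reads
#'
#' Full allele-specific calling pipeline: global alignment of each unique
#' read sequence, haplotype clustering over the cut-site window, variant
#' calling with blacklist removal, consequence annotation and dosage.
#'
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `sequence` column (as from [simulate_amplicon_reads()]).
#' @param target An [amplicon_target()].
#' @param embryo_id Identifier carried into the result.
#' @param min_support_fraction,min_support_reads,cut_window Passed to
#'   [cluster_haplotypes()] / [call_variants()].
#' @return Object of class `site_call`: list with `embryo_id`, `target`,
#'   `status`, `reason`, `alleles` (each with `haplotype`, `support`,
#'   `variants` incl. `category`/`impact`/`weight`, `allele_weight`),
#'   `dosage`, `n_reads`, `n_unmappable`.
#' @export
call_site <- function(reads, target, embryo_id = "embryo",
                      min_support_fraction = 0.10, min_support_reads = 5L,
                      cut_window = .bc_defaults$cut_window_bp) {
  if (is.data.frame(reads)) reads <- reads$sequence
  stopifnot(length(reads) >= 1)
  uniq <- unique(reads)
  alns <- lapply(uniq, align_read, target = target)
  ok <- vapply(alns, `[[`, logical(1), "mappable")
  n_unmappable <- sum(!reads %in% uniq[ok])
  if (any(!ok))
    message(sum(!ok), " unique read sequence(s) unmappable; discarded")
  uvars <- lapply(which(ok), function(i)
    variants_from_ops(uniq[i], alns[[i]]$ops, target))
  map <- match(reads, uniq[ok])
  read_variants <- uvars[map[!is.na(map)]]
  cl <- cluster_haplotypes(read_variants, target,
                           min_support_fraction, min_support_reads, cut_window)
  call <- list(embryo_id = embryo_id, target = target$name,
               status = cl$status, reason = cl$reason, alleles = list(),
               dosage = NA_real_, n_reads = length(reads),
               n_unmappable = n_unmappable)
  if (cl$status == "called") {
    call$alleles <- lapply(cl$alleles, function(a) {
      v <- call_variants(a, target, cut_window)
      if (nrow(v)) {
        ann <- lapply(seq_len(nrow(v)), function(i)
          annotate_consequence(v[i, ], target))
        v$category <- vapply(ann, `[[`, "", "category")
        v$impact <- vapply(ann, `[[`, "", "impact")
        v$weight <- vapply(ann, `[[`, numeric(1), "weight")
      } else {
        v$category <- character(0); v$impact <- character(0)
        v$weight <- numeric(0)
      }
      a$variants <- v
      a$allele_weight <- if (nrow(v)) max(v$weight) else 0
      a
    })
    call <- structure(call, class = "site_call")
    call$dosage <- site_dosage(call)
    return(call)
  }
  structure(call, class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat("site_call", x$embryo_id, "@", x$target, ":", x$status)
  if (x$status == "called") {
    cat(", dosage", x$dosage, ", allele supports",
        paste(vapply(x$alleles, `[[`, integer(1), "support"), collapse = "/"))
  } else cat(" (", x$reason, ")", sep = "")
  cat("\n")
  invisible(x)
}
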