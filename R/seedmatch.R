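#' Mature miRNA constructor
#'
#' Validates and normalizes a mature miRNA sequence (5'->3'). DNA-alphabet
#' input is accepted: `T` is normalized to `U`.
#'
#' @param name miRNA name.
#' @param sequence RNA (or DNA) string of length >= 8.
#' @return list of class `mature_mirna` with `name` and `sequence`.
#' @export
mature_mirna <- function(name, sequence) {
  seq <- toupper(gsub("T", "U", toupper(sequence)))
  abort_if(nchar(seq) < 8, "mature miRNA sequence must be >= 8 nt")
  abort_if(grepl("[^ACGU]", seq),
           "sequence may only contain A/C/G/U (or T on input)")
  structure(list(name = name, sequence = seq), class = "mature_mirna")
}

rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Canonical seed-site patterns of a miRNA
#'
#' Derives the UTR-sense (5'->3') patterns of the four canonical target
#' site classes from the miRNA's seed (positions 2-8):
#' `7mer-m8` = reverse complement of positions 2-8; `8mer` = that pattern
#' followed by `A` (the anchoring adenosine opposite position 1);
#' `6mer` = reverse complement of positions 2-7; `7mer-A1` = the 6mer
#' followed by `A`.
#'
#' @param mirna a [mature_mirna()] (or character sequence).
#' @return named character vector with entries `8mer`, `7mer-m8`,
#'   `7mer-A1`, `6mer`, in the RNA alphabet.
#' @examples
#' seed_patterns(mature_mirna("let-7", "UGAGGUAGUAGGUUGUAUAGUU"))
#' @export
seed_patterns <- function(mirna) {
  if (is.character(mirna)) mirna <- mature_mirna("miRNA", mirna)
  s <- mirna$sequence
  seed78 <- substr(s, 2, 8)
  seed27 <- substr(s, 2, 7)
  c(`8mer` = paste0(rna_revcomp(seed78), "A"),
    `7mer-m8` = rna_revcomp(seed78),
    `7mer-A1` = paste0(rna_revcomp(seed27), "A"),
    `6mer` = rna_revcomp(seed27))
}

#' Knuth-Morris-Pratt prefix function
#'
#' Length of the longest proper border (prefix that is also a suffix) of
#' every prefix of `pattern`.
#'
#' @param pattern nonempty string.
#' @return integer vector of the same length as the pattern.
#' @export
kmp_prefix_function <- function(pattern) {
  abort_if(!nzchar(pattern), "`pattern` must be nonempty")
  p <- strsplit(pattern, "")[[1]]
  m <- length(p)
  pi <- integer(m)
  k <- 0L
  for (i in 2:max(2L, m)) {
    if (m < 2) break
    while (k > 0L && p[k + 1L] != p[i]) k <- pi[k]
    if (p[k + 1L] == p[i]) k <- k + 1L
    pi[i] <- k
  }
  pi
}

#' Knuth-Morris-Pratt substring search
#'
#' Linear-time search for all (possibly overlapping) occurrences of
#' `pattern` in `text`. Case-insensitive; `U` and `T` are equivalent, so
#' RNA patterns match DNA-alphabet text and vice versa.
#'
#' @param pattern nonempty string.
#' @param text string to scan.
#' @return integer vector of 1-based match start positions.
#' @examples
#' kmp_search("ACA", "ACACACA")
#' @export
kmp_search <- function(pattern, text) {
  abort_if(!nzchar(pattern), "`pattern` must be nonempty")
  norm <- function(x) gsub("T", "U", toupper(x))
  p <- strsplit(norm(pattern), "")[[1]]
  t <- strsplit(norm(text), "")[[1]]
  m <- length(p); n <- length(t)
  if (m > n) return(integer(0))
  pi <- kmp_prefix_function(norm(pattern))
  hits <- integer(0)
  q <- 0L
  for (i in seq_len(n)) {
    while (q > 0L && p[q + 1L] != t[i]) q <- pi[q]
    if (p[q + 1L] == t[i]) q <- q + 1L
    if (q == m) {
      hits <- c(hits, i - m + 1L)
      q <- pi[q]
    }
  }
  hits
}

site_type_order <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Scan a 3' UTR for miRNA seed-match sites
#'
#' Searches the UTR for all four canonical site patterns via [kmp_search()]
#' and resolves overlapping hits by type precedence
#' `8mer > 7mer-m8 > 7mer-A1 > 6mer` (then leftmost start): a stronger
#' site consumes its window, so e.g. an 8mer is not additionally reported
#' as the 7mers it contains. Coordinates are 1-based inclusive on the UTR.
#' 6mer sites are reported only when `include_6mer = TRUE`.
#'
#' @param mirna a [mature_mirna()].
#' @param utr a single named character string (the UTR sequence), or an
#'   `XStringSet`/named character vector of several UTRs.
#' @param include_6mer report 6mer sites?
#' @param with_features also compute [context_features()] per site?
#' @return data frame with columns `transcript`, `start`, `end`,
#'   `site_type`, and, when `with_features = TRUE`, `local_au`,
#'   `distance_to_end`, `supp_pairing`, `simple_context_score`.
#' @export
scan_utr <- function(mirna, utr, include_6mer = FALSE, with_features = FALSE) {
  seqs <- utr_as_character(utr)
  pats <- seed_patterns(mirna)
  rows <- list()
  for (id in names(seqs)) {
    text <- seqs[[id]]
    hits <- do.call(rbind, lapply(site_type_order, function(ty) {
      st <- kmp_search(pats[[ty]], text)
      if (length(st) == 0) return(NULL)
      data.frame(start = st, end = st + nchar(pats[[ty]]) - 1L,
                 site_type = ty, stringsAsFactors = FALSE)
    }))
    if (is.null(hits)) next
    hits$prec <- match(hits$site_type, site_type_order)
    hits <- hits[order(hits$prec, hits$start), , drop = FALSE]
    taken <- rep(FALSE, nchar(text))
    keep <- logical(nrow(hits))
    for (r in seq_len(nrow(hits))) {
      win <- hits$start[r]:hits$end[r]
      if (!any(taken[win])) {
        keep[r] <- TRUE
        taken[win] <- TRUE
      }
    }
    hits <- hits[keep, c("start", "end", "site_type"), drop = FALSE]
    if (nrow(hits) > 0) {
      hits <- cbind(transcript = id, hits, stringsAsFactors = FALSE)
      rows[[id]] <- hits
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE)
  }
  if (!include_6mer) out <- out[out$site_type != "6mer", , drop = FALSE]
  out <- out[order(out$transcript, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (with_features && nrow(out) > 0) {
    feats <- do.call(rbind, lapply(seq_len(nrow(out)), function(r) {
      site <- out[r, ]
      as.data.frame(context_features(site, mirna, seqs[[site$transcript]]))
    }))
    out <- cbind(out, feats)
  }
  out
}

utr_as_character <- function(utr) {
  nms <- names(utr)
  seqs <- as.character(utr)  # drops plain-vector names; restore below
  names(seqs) <- if (is.null(nms)) paste0("seq", seq_along(seqs)) else nms
  vapply(seqs, function(x) gsub("T", "U", toupper(x)), character(1))
}

# Default weights of the simplified context score. These are fixed,
# documentation-level surrogates that reproduce only the canonical type
# ordering (8mer strongest); they are NOT the trained context++ model and
# the resulting scores are not comparable to published context++ values.
context_weights <- function() {
  list(type = c(`8mer` = -0.31, `7mer-m8` = -0.16, `7mer-A1` = -0.10,
                `6mer` = -0.03),
       au = -0.06, supp = -0.03, dist = 0.05)
}

#' Simplified context features of a seed-match site
#'
#' Computes the classic site-context features: local AU content (fraction
#' of A/U in the 30 nt flanking each side of the site, truncated at the
#' UTR ends), distance to the nearest UTR end (`min(start - 1, L - end)`),
#' and 3'-supplementary pairing (longest contiguous Watson-Crick run
#' between miRNA positions 13-16 and the UTR region opposite them). The
#' simple context score is a fixed-weight linear combination; more
#' negative = stronger site.
#'
#' @param site one row of a [scan_utr()] result (needs `start`, `end`,
#'   `site_type`).
#' @param mirna a [mature_mirna()].
#' @param utr the UTR sequence (single character string).
#' @return list with `local_au`, `distance_to_end`, `supp_pairing`,
#'   `simple_context_score`.
#' @export
context_features <- function(site, mirna, utr) {
  utr <- gsub("T", "U", toupper(utr))
  L <- nchar(utr)
  start <- as.integer(site$start); end <- as.integer(site$end)
  abort_if(start < 1 || end > L || start > end,
           "site coordinates fall outside the UTR")
  flank <- c(substr(utr, max(1, start - 30), start - 1),
             substr(utr, end + 1, min(L, end + 30)))
  fl <- strsplit(paste(flank, collapse = ""), "")[[1]]
  local_au <- if (length(fl) == 0) 0 else mean(fl %in% c("A", "U"))
  dist <- min(start - 1L, L - end)
  supp <- supp_pairing_run(mirna, utr, start, end, site$site_type)
  w <- context_weights()
  score <- unname(w$type[[site$site_type]]) +
    w$au * (local_au - 0.5) +
    w$supp * supp / 4 +
    w$dist * min(dist, 1500) / 1500
  list(local_au = local_au, distance_to_end = dist, supp_pairing = supp,
       simple_context_score = score)
}

# Longest contiguous Watson-Crick run between miRNA positions 13-16 and
# the UTR nucleotides opposite them (immediately 5' of the seed match on
# the UTR, read antiparallel).
supp_pairing_run <- function(mirna, utr, start, end, site_type) {
  if (is.character(mirna)) mirna <- mature_mirna("miRNA", mirna)
  ms <- strsplit(mirna$sequence, "")[[1]]
  if (length(ms) < 16) return(0L)
  # UTR position opposite miRNA position 1 for this site
  seed_end_utr <- if (site_type %in% c("8mer", "7mer-A1")) end - 1L else end
  pos1_utr <- seed_end_utr + 1L
  run <- 0L; best <- 0L
  for (k in 13:16) {
    up <- pos1_utr - (k - 1L)  # UTR base opposite miRNA position k
    if (up < 1 || up > nchar(utr)) { run <- 0L; next }
    ub <- substr(utr, up, up)
    if (wc_pair(ms[k], ub)) {
      run <- run + 1L
      best <- max(best, run)
    } else {
      run <- 0L
    }
  }
  best
}

wc_pair <- function(a, b) {
  (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
}

#' Read UTR sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning a named
#' character vector in the RNA alphabet.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  utr_as_character(x)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_utr_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
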