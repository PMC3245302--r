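# Shared fixtures (memoized: the default locus and pools are reused across
# files) and independent oracles used by the property tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

default_ref <- function() fixture("ref", build_reference(seed = 20))

default_allele <- function() fixture("allele", build_fm_allele(default_ref()))

default_cohort <- function() {
  fixture("cohort", simulate_array_cohort(default_ref(), default_allele(),
                                          array_cohort_spec(seed = 1)))
}

default_pools <- function() {
  fixture("pools", list(
    case = simulate_matepair_pool(default_allele(), pool_spec(seed = 101)),
    ctrl = simulate_matepair_pool(default_ref(), pool_spec(seed = 202))
  ))
}

# small reference for junction and sequence-level tests (fast to build)
tiny_ref <- function(overlap_5p = 0, overlap_3p = 1, seed = 5) {
  build_reference(chrom = "toy",
                  locus = c(1001, 15000),
                  d1 = c(4001, 6500),
                  d2 = c(9501, 12000),
                  overlap_5p = overlap_5p, overlap_3p = overlap_3p,
                  seed = seed)
}

## ---- oracle: exhaustive least-squares changepoint search -------------------
# Best segmentation of x into k+1 pieces (k changepoints) minimizing RSS,
# by full enumeration. Returns the boundary indices (last index of each piece
# except the final one). Independent of the segmentation implementation.
ls_changepoints <- function(x, k) {
  n <- length(x)
  rss <- function(v) sum((v - mean(v))^2)
  if (k == 0) return(integer(0))
  cuts <- utils::combn(seq_len(n - 1), k)
  best <- NULL
  best_rss <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    total <- sum(vapply(seq_len(length(b) - 1),
                        function(i) rss(x[(b[i] + 1):b[i + 1]]), numeric(1)))
    if (total < best_rss) {
      best_rss <- total
      best <- cuts[, j]
    }
  }
  best
}

## ---- oracle: brute-force junction breakpoint/overlap search ----------------
# Maximal fragment prefix (suffix) occurring anywhere in the reference or its
# reverse complement, found by binary search over the prefix length (substring
# occurrence is monotone in length). Microhomology and inserted sequence
# follow from the two maximal lengths alone.
oracle_junction <- function(fragment, refseq) {
  rc <- dermadup:::revcomp(refseq)
  occurs <- function(s) grepl(s, refseq, fixed = TRUE) || grepl(s, rc, fixed = TRUE)
  n <- nchar(fragment)
  max_len <- function(get_sub) {
    lo <- 1; hi <- n
    while (lo < hi) {
      mid <- ceiling((lo + hi) / 2)
      if (occurs(get_sub(mid))) lo <- mid else hi <- mid - 1
    }
    lo
  }
  p_len <- max_len(function(k) substr(fragment, 1, k))
  s_len <- max_len(function(k) substr(fragment, n - k + 1, n))
  list(
    prefix_len = p_len,
    suffix_len = s_len,
    microhomology_len = max(0L, p_len + s_len - n),
    inserted_len = max(0L, n - p_len - s_len)
  )
}
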