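# Fixtures built in code: record sets whose margins equal the published
# national-survey tables, plus small helpers shared across test files.

# A 34,837-row response set with the published per-question yes/no counts
# AND the published sufficient/insufficient split (20,611 / 14,226).
# The 20,611 sufficient rows are all-yes; the "no" answers are packed into
# the insufficient rows so that every insufficient row has at least one no.
make_national_knowledge_records <- function() {
  n_suff <- 20611L
  n_insuff <- 14226L
  no <- c(heard_hiv = 1L, mtct_pregnancy = 7950L, mtct_delivery = 6166L,
          mtct_breastfeeding = 1993L, knows_pmtct_drugs = 5138L)
  m <- matrix(1L, n_insuff, 5L,
              dimnames = list(NULL, names(no)))
  m[seq_len(no["mtct_pregnancy"]), "mtct_pregnancy"] <- 0L
  m[no["mtct_pregnancy"] + seq_len(no["mtct_delivery"]), "mtct_delivery"] <- 0L
  # remaining rows (those with pregnancy and delivery both yes) need a no:
  rest <- (no["mtct_pregnancy"] + no["mtct_delivery"] + 1L):n_insuff
  m[rest, "mtct_breastfeeding"] <- 0L
  m[seq_len(no["mtct_breastfeeding"] - length(rest)), "mtct_breastfeeding"] <- 0L
  m[seq_len(no["knows_pmtct_drugs"]), "knows_pmtct_drugs"] <- 0L
  m[1L, "heard_hiv"] <- 0L
  suff <- matrix(1L, n_suff, 5L, dimnames = list(NULL, names(no)))
  as.data.frame(rbind(suff, m))
}

# Covariate columns with the published level counts (n = 34,837 rows).
# Two published covariate blocks are internally inconsistent with the
# overall n (marital sums to 34,836; newspaper to 34,866): columns short
# of n are padded with NA (excluded from the per-covariate denominator)
# and newspaper keeps its published yes count against the overall n,
# which still rounds to the printed 16.5%.
make_national_covariate_records <- function() {
  n <- 34837L
  rep_counts <- function(counts) {
    stopifnot(sum(counts) <= n)
    c(rep(names(counts), times = counts), rep(NA, n - sum(counts)))
  }
  data.frame(
    residence = rep_counts(c(urban = 14625L, rural = 20212L)),
    marital = rep_counts(c(never_married = 8409L, ever_married = 26427L)),
    ethnicity = rep_counts(c(others = 13301L, hausa_fulani = 11097L,
                             igbo = 5970L, yoruba = 4469L)),
    newspaper = rep_counts(c(yes = 5744L, no = 29093L)),
    stringsAsFactors = FALSE
  )
}

# response row constructor: five binary answers in question order
resp_row <- function(v) {
  stats::setNames(as.data.frame(as.list(as.integer(v))),
                  knowledge_questions())
}

# all 32 possible complete response vectors
all_response_vectors <- function() {
  g <- expand.grid(rep(list(0:1), 5))
  names(g) <- knowledge_questions()
  g
}

# Monte Carlo standard errors: posterior mean and quantile (normal approx)
mcse_mean <- function(draws) sd(draws) / sqrt(ess(draws))
mcse_q <- function(draws, p) {
  sd(draws) * sqrt(p * (1 - p) / ess(draws)) / dnorm(qnorm(p))
}
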