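# Shared builders for engine tests: pools of pass-through evidence items
# (the engine accepts any code; only category and applied strength matter)
# and a profile builder from strength-slot counts.

item_pool <- function(prefix, strength, n = 4) {
  lapply(seq_len(n), function(i) evidence_item(paste0(prefix, "X", i), strength))
}

POOL <- list(
  vs = item_pool("P", "very_strong"),
  s  = item_pool("PS", "strong"),
  m  = item_pool("PM", "moderate"),
  p  = item_pool("PP", "supporting"),
  sa = item_pool("BA", "stand_alone"),
  bs = item_pool("BS", "strong"),
  bp = item_pool("BP", "supporting")
)

profile_from_counts <- function(vs = 0, s = 0, m = 0, p = 0,
                                sa = 0, bs = 0, bp = 0) {
  evidence_profile(items = c(
    POOL$vs[seq_len(vs)], POOL$s[seq_len(s)], POOL$m[seq_len(m)],
    POOL$p[seq_len(p)], POOL$sa[seq_len(sa)], POOL$bs[seq_len(bs)],
    POOL$bp[seq_len(bp)]
  ))
}

# Independent oracle: the ACMG/AMP combining rules transcribed directly as
# vectorized boolean predicates over strength-slot counts.
oracle_combine <- function(vs, s, m, p, sa, bs, bp) {
  path <- (vs >= 1 & (s >= 1 | m >= 2 | (m == 1 & p == 1) | p >= 2)) |
    s >= 2 |
    (s == 1 & (m >= 3 | (m == 2 & p >= 2) | (m == 1 & p >= 4)))
  lp <- (vs == 1 & m == 1) |
    (s == 1 & m >= 1 & m <= 2) |
    (s == 1 & p >= 2) |
    m >= 3 | (m == 2 & p >= 2) | (m == 1 & p >= 4)
  ben <- sa >= 1 | bs >= 2
  lb <- (bs == 1 & bp >= 1) | bp >= 2
  has_path <- (vs + s + m + p) > 0
  has_ben <- (sa + bs + bp) > 0
  conflict <- has_path & has_ben & (path | lp | ben | lb)
  tier <- ifelse(conflict, "uncertain_significance",
          ifelse(path, "pathogenic",
          ifelse(lp, "likely_pathogenic",
          ifelse(ben, "benign",
          ifelse(lb, "likely_benign", "uncertain_significance")))))
  rationale <- ifelse(conflict, "evidence_in_conflict",
               ifelse(tier == "uncertain_significance",
                      "insufficient_evidence", "no_conflict"))
  data.frame(tier = tier, rationale = rationale, stringsAsFactors = FALSE)
}

# The eight published evidence profiles (one per tested variant), built
# directly from their code sets.
table4_profile <- function(which) {
  ps3 <- evidence_item("PS3", "strong", "supporting")
  pm2 <- evidence_item("PM2", "moderate", "supporting")
  pm3 <- evidence_item("PM3", "moderate")
  pm5 <- evidence_item("PM5", "moderate")
  pp3 <- evidence_item("PP3", "supporting")
  pp4 <- evidence_item("PP4", "supporting", "moderate")
  bs1 <- evidence_item("BS1", "strong")
  bp4 <- evidence_item("BP4", "supporting")
  switch(which,
    "c.316C>T"  = evidence_profile(ps3, pm2, pm3, pp4),
    "c.1103G>A" = evidence_profile(ps3, pm2, pm3, pp4),
    "c.1721T>C" = evidence_profile(ps3, pm2, pm3, pp3, pp4),
    "c.664G>A"  = evidence_profile(bs1, bp4, pp4),
    "c.2450A>G" = evidence_profile(ps3, pm2, pp3, pp4),
    "c.1048G>A" = evidence_profile(ps3, pm2, pm3, pp3, pp4),
    "c.1378G>A" = evidence_profile(pm2, pm3, pp4),
    "c.1123C>T" = evidence_profile(pm2, pm3, pm5, pp3, pp4),
    stop("unknown variant")
  )
}

TIER_ORDER <- c(benign = 1, likely_benign = 2, uncertain_significance = 3,
                likely_pathogenic = 4, pathogenic = 5)
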