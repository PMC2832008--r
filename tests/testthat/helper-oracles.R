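# Independent reference implementations used to cross-check the package.

# Tier-merge reference for the digital transform: means of the three stages
# and a p-value lookup between stage indices.
digitalOracle <- function(means, pfun, alpha = 0.01) {
  ord <- order(means, seq_along(means))
  tier <- integer(3); tier[ord[1]] <- 1L; repr <- ord[1]
  for (j in 2:3) {
    if (pfun(repr, ord[j]) < alpha) {
      tier[ord[j]] <- tier[repr] + 1L; repr <- ord[j]
    } else tier[ord[j]] <- tier[repr]
  }
  tier
}

# Exact rational-arithmetic two-sided Fisher p in log space, computed with
# Python's fractions module (arbitrary-precision rationals). Input: matrix
# with columns a, b, c, d; returns log(p) per row.
rationalFisherLogP <- function(tables) {
  script <- '
import sys, math
from fractions import Fraction
for line in sys.stdin:
    a, b, c, d = map(int, line.split())
    m, n, k = a + b, c + d, a + c
    denom = math.comb(m + n, k)
    lo, hi = max(0, k - n), min(k, m)
    probs = [Fraction(math.comb(m, x) * math.comb(n, k - x), denom)
             for x in range(lo, hi + 1)]
    pobs = probs[a - lo]
    cut = pobs * Fraction(10000001, 10000000)
    p = sum(pr for pr in probs if pr <= cut)
    print(repr(math.log(p.numerator) - math.log(p.denominator)))
'
  inp <- apply(tables, 1L, paste, collapse = " ")
  out <- system2("python", c("-c", shQuote(script)), input = inp,
                 stdout = TRUE)
  as.numeric(out)
}
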