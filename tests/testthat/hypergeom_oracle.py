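"""Exact-rational hypergeometric upper-tail oracle.

Reads tab-separated instances "k a b N" from the file given as argv[1] and
prints one exact tail probability per line,
    P(K >= k) = sum_{i=k}^{min(a,b)} C(b,i) C(N-b,a-i) / C(N,a),
computed with integer binomials and Fraction arithmetic, then converted to
float only for output. Shares nothing with the R implementation.
"""
import sys
from fractions import Fraction
from math import comb

with open(sys.argv[1]) as fh, open(sys.argv[2], "w") as out:
    for line in fh:
        k, a, b, n = map(int, line.split())
        denom = comb(n, a)
        total = sum(comb(b, i) * comb(n - b, a - i)
                    for i in range(k, min(a, b) + 1))
        p = Fraction(total, denom)
        out.write(repr(float(p)) + "\n")
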