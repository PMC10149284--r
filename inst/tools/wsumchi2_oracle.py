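"""Multiple-precision oracle for the weighted sum-of-chi-squared tail.

Evaluates P(sum_j lambda_j W_j >= t) for iid central chi2(1) W_j with
mpmath arbitrary-precision arithmetic, using the chi-squared mixture series
with shape beta = lambda_min / 2 (a different shape than the package's
evaluator, and mpmath's own regularized incomplete gamma), and prints
-log10(p).  Usage:

    python wsumchi2_oracle.py digits t lambda1 [lambda2 ...]
"""
import sys
from mpmath import mp, mpf, log, exp, gammainc, log10


def wsum_sf(lam, t, digits):
    mp.dps = digits + 15
    lam = [mpf(x) for x in lam]
    t = mpf(t)
    m = len(lam)
    beta = min(lam) / 2
    x = t / beta
    rho = [1 - beta / l for l in lam]
    a = [exp(sum(log(beta / l) for l in lam) / 2)]
    half = mpf(1) / 2
    # chi2 survival at df m + 2k via mpmath regularized upper gamma
    sf = gammainc(m * half, x * half, mp.inf, regularized=True)
    u = exp((m * half) * log(x * half) - x * half) / gammainc(m * half + 1)
    S = a[0] * sf
    mass = a[0]
    g = [mpf(m)]
    rp = rho[:]
    tol = mpf(10) ** (-digits - 5)
    prev = None
    streak = 0
    rho_max = max(rho)
    for k in range(1, 2000000):
        sf = sf + u
        u = u * (x * half) / (m * half + k)
        g.append(sum(rp))
        for j in range(m):
            rp[j] *= rho[j]
        ak = sum(g[k - r] * a[r] for r in range(k)) / (2 * k)
        a.append(ak)
        term = ak * sf
        S += term
        mass += ak
        rem = 1 - mass
        if rem > 0 and rem <= tol * S:
            break
        if prev is not None and term < prev:
            streak += 1
            q = max(term / prev, rho_max)
            if streak >= 4 and term * q / (1 - q) <= tol * S:
                break
        else:
            streak = 0
        prev = term
    return S


if __name__ == "__main__":
    digits = int(sys.argv[1])
    t = sys.argv[2]
    lam = sys.argv[3:]
    S = wsum_sf(lam, t, digits)
    mp.dps = digits
    print(-log10(S))
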