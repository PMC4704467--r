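---
title: "Counting similar compounds without sharing them: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting similar compounds without sharing them: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscc)
```

## The problem

A client holds a candidate compound; a server holds a fingerprint
database. The client wants to know how many database compounds are
similar to its candidate — a routine pre-screening question — but neither
party can show the other its data. `sscc` solves exactly this: the client
learns one integer, the count of database fingerprints whose Tversky
similarity to the query is at least a threshold θ, and the server learns
nothing about the query beyond its length.

Fingerprints are bit vectors of fixed length ℓ; the default ℓ = 166
matches the ubiquitous MACCS key set. We write |p| for a fingerprint's
popcount and |p ∩ q| for the overlap.

## From a rational predicate to an integer sign

The Tversky index
TI(p, q) = |p∩q| / (|p∩q| + α|p\q| + β|q\p|)
is a ratio, and homomorphic encryption handles sums, not divisions. With
all parameters rational — α = μa/γ, β = μb/γ, θ = θn/θd — the predicate
TI ≥ θ can be cleared of denominators. `derive_lambdas()` computes

* g = gcd(γ(θd − θn) + θn(μa + μb), θn·μa, θn·μb),
* λ1 = (γ(θd − θn) + θn(μa + μb))/g, λ2 = θn·μa/g, λ3 = θn·μb/g,

and `threshold_tversky()` evaluates the integer score
λ1|p∩q| − λ2|p| − λ3|q|, which is ≥ 0 exactly when TI ≥ θ. All arithmetic
here is exact integer/rational arithmetic; no floating point touches a
sign decision. For the standard chemical-search setting (Jaccard, θ =
4/5) the λ parameters are (9, 4, 4) and the score of 166-bit pairs spans
exactly [−664, 166]:

```{r}
lam <- derive_lambdas(tversky_params())
lam
score_range(166, lam)
```

`score_range()` enumerates all feasible cardinality triples (a, b, c)
with max(0, a + b − ℓ) ≤ c ≤ min(a, b); since the score is linear in c
only the interval endpoints matter, so the enumeration is ~ℓ² cells and
instantaneous. Two boundary conventions are worth stating:

* **k counts the integer interval, not attainable values.** The dummy
  domain size k = max − min + 1 (831 above) includes interior integers
  that no fingerprint pair attains. The uniform-dummy privacy analysis is
  phrased over this interval, and the protocol adopts it as the dummy
  domain.
* **The empty/empty pair.** TI is 0/0 when both fingerprints are empty,
  but the integer score is total and equals 0, so the protocol counts the
  pair as similar. `count_similar()`, the plaintext oracle, follows the
  same convention; the sign-equivalence tests exclude this single
  undefined point.

## The cryptographic layer

The additively homomorphic scheme is lifted ElGamal over a named
prime-order elliptic-curve group (default secp192k1, a 192-bit curve):
Enc(m; r) = (rG, r·PK + mG). Plaintexts ride in the exponent, so
ciphertexts add (⊕) and scale by known integers (⊗) without the secret
key. Negative messages are encoded directly as group inversions — the
score is a signed quantity — and decryption solves a small discrete
logarithm over a caller-supplied interval via a precomputed table (the
interval is a few thousand values at most in this protocol; a plaintext
outside it raises a decode-failure error, which is the correct behaviour
for a malformed or hostile reply). The group abstraction is pluggable by
curve name; the group arithmetic and hashing come from OpenSSL's
libcrypto, while the scheme, decoding and protocol logic are implemented
in the package.

Each encrypted query bit carries a non-interactive zero-knowledge proof
that its plaintext is 0 or 1. The construction is the standard two-branch
disjunctive Chaum–Pedersen sigma protocol ("C encrypts 0" OR "C encrypts
1"), made non-interactive with a Fiat–Shamir challenge: SHA-256 over a
domain-separated serialization of (curve, public key, ciphertext,
commitments), reduced mod the group order. This satisfies the same
contract as the scheme the protocol was designed around: completeness for
honest bits, soundness against any non-bit plaintext, and zero-knowledge
(the tests exercise the special-honest-verifier simulator against the
interactive verifier; a Fiat–Shamir simulator would need to program the
random oracle, so simulated transcripts deliberately fail the
non-interactive verifier). Proofs are bound to the exact ciphertext and
public key by including both in the hash.

Why this matters: without the proof, a malicious client can submit an
encryption of, say, 10⁶ at position i and zeros elsewhere; the returned
score is then dominated by that term and reveals the database bit p_i,
dummies notwithstanding. `verify_query()` rejects such queries before any
scoring happens.

## The protocol round

One message each way:

1. Client: encrypt the ℓ query bits, attach ℓ bit proofs, send.
2. Server: verify all proofs or abort. Homomorphically assemble, per
   database entry, Enc(λ1|p∩q| − λ2|p| − λ3|q|): Enc(|p∩q|) is the sum of
   the query-bit ciphertexts selected by the entry, Enc(−|q|) is derived
   from the query itself (the server never asks the client for it — a
   client-supplied Enc(−|q|) would need its own validity proof), and
   Enc(−|p|) is encrypted server-side. Every score ciphertext is
   rerandomized before release so its bytes carry no trace of how it was
   assembled.
3. Server: draw n dummy values from the dummy domain (default: uniform
   over the score interval), encrypt them, shuffle dummies and scores
   together, and send the multiset plus s_d, the number of non-negative
   dummies. Zero counts as non-negative throughout.
4. Client: decrypt everything, count non-negatives s_c, report
   s_c − s_d.

Correctness is exact: s_c − s_d equals the number of entries with score
≥ 0, which is the number with TI ≥ θ. The decode interval for step 4 is
the union of the score range and the dummy domain, so an honest run can
never hit a decode failure.

## What the attack simulators measure

All simulators run on plaintext scores: they quantify information
disclosure, which is unchanged by the (semantically secure) encryption,
and plaintext simulation lets 10⁵-trial experiments finish in seconds.

**Regression attack** (`plain_score_attack`). If the server returned the
exact score, the difference score(e_i) − score(0) between a unit-vector
probe and the all-zero baseline is positive iff p_i = 1. One baseline
plus ℓ probes recover the entry exactly — 167 queries at ℓ = 166. This is
the benchmark the sign-only design is measured against.

**Hit probability** (`hit_probability`). Against a sign-only server the
known linear follow-up attack needs a foothold: a "hit" query with
strictly positive score. The estimator draws queries from a pluggable
sampler (default: uniform fingerprints, each bit a fair coin — the query
distribution of the underlying analysis is not pinned down, so the
sampler is an argument), estimates f_p = Pr(score > 0), and returns
1 − (1 − f_p)^x. A `strict` switch controls the boundary: the hit
definition is strictly positive, under which θ = 1 admits no hit at all
(the only threshold-meeting query, q = p, scores exactly 0);
`strict = FALSE` counts the boundary too and gives the closed form 2^−ℓ
at θ = 1, which the tests use as an oracle.

**Dummy guessing** (`dummy_guess_experiment`). The adversary model: a
single-entry database, k possible score values, the true score drawn from
a prior w the attacker knows, dummies uniform over the k values (also
known to the attacker). Receiving value i a_i times across the n + 1
items, the posterior for the true score is proportional to a_i·w_i, so
the attacker's best strategy is argmax a_i·w_i — and argmax of the
product across L repeated queries in the multi-query case, accumulated in
log space. Argmax ties are broken uniformly at random; ties are detected
with a 1e−12 relative tolerance because the scores mix exact integer
counts with double-precision weights. Each trial draws the truth from w
and the dummy counts as one multinomial vector (distributionally
identical to n individual draws, far faster), then checks the guess.
Success is 1.0 with no dummies, falls as n grows, and converges to the
leak-free ideal max_i w_i — the padding-privacy pattern:

```{r}
w <- rand_prior(831, seed = 1)      # the synthetic prior recipe: 5k draws
ratios <- sapply(c(0, 831, 83100), function(n)
  dummy_guess_experiment(w, n, trials = 2000, seed = 2))
rbind(n = c(0, 831, 83100), success = round(ratios, 4))
max(w)                              # the ideal
```

Because the reference priors derived from a proprietary compound
collection are not reproducible without that dataset, the package ships
two synthetic substitutes: `rand_prior()` (frequencies of 5k uniform
draws over the k values, the published synthetic recipe) and
`empirical_score_prior()` (the score distribution induced by the
package's own fingerprint generator). The corresponding experiment is
therefore checked as a trend — exact at n = 0, monotone within
Monte-Carlo noise, within three standard errors of max w at heavy
padding — not against printed cells.

**Perturbed dummies** (`perturbed_dummy_distribution`). To ask how
precisely an attacker must know the dummy distribution, dummies can be
drawn from u_i ∝ max(0, r_i)/k with r_i ~ N(1, δ²) while the attacker
still assumes uniformity. Negative draws are truncated and the weights
renormalized (the construction does not state normalization; a
distribution must sum to one, so it is applied and flagged here).

## Synthetic data: what it does and does not emulate

`random_fingerprints()` draws i.i.d. Bernoulli bits, default density 0.3
— a realistic marginal sparsity for MACCS-style keys (popcount ≈ 50 of
166). An optional blockwise-correlated mode crudely mimics the positive
correlation of neighbouring structural keys but is not used by any test.
What passing tests show: the protocol, its counting, and the simulators
are exact for *any* valid fingerprints, since correctness is
combinatorial and never depends on the bit distribution. What they do not
show: realistic *magnitudes* for data-dependent quantities (hit
probabilities, score priors w) on real compound collections — those would
shift with real correlation structure, though the qualitative patterns
(full recovery at ℓ+1 queries, convergence to max w) would not.

The FPS-style reader/writer uses the chemfp-compatible convention — bit 0
is the least significant bit of its byte, bytes left to right, pad bits
zero — fixed once because interoperable files need one convention.

## Numerical and operational choices

* Seeds are honoured everywhere for reproducibility, but the seeded path
  derives scalars from R's RNG and is test-only; with no seed all
  cryptographic randomness comes from OpenSSL's RNG. `protocol_config()`
  refuses a seed unless the policy is explicitly `"test"`.
* The dummy count defaults to n = 10,000, the protocol's published
  operating point; the dummy domain defaults to the score interval.
* Decode tables are built per decryption call (hundreds to thousands of
  group additions — negligible against the scalar multiplications the
  call already does); the table covers score range ∪ dummy domain so
  honest runs cannot fail.
* Test problem sizes: the end-to-end equivalence suite runs 100 random
  instances at ℓ = 166 with up to 200 entries and up to 1000 dummies, and
  the guessing experiments use 10,000 trials at k = 831 with paddings up
  to 100k — sizes chosen so the whole suite completes in a few minutes on
  one core while still exercising the full-scale parameter set.

## Known limitations

* The protocol returns a count only; returning the matching compounds, or
  extracting the sign by bitwise decomposition instead of dummies, are
  different protocols and out of scope.
* Side channels (timing, message sizes beyond the padded count) and
  formal security proofs are not addressed; the security analyses here
  are empirical simulators.
* The disjunctive bit proof is contract-equivalent to, but not
  transcript-compatible with, the scheme the design originally named.
* Perturbed-dummy experiments always model an attacker who assumes
  uniform dummies, matching the experimental design they reproduce.
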