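# sscc — Secure Similar Compounds Counter

Pharmaceutical fingerprint databases are valuable and sensitive on both
sides: a client does not want to reveal the compound it is screening, and a
database holder does not want its entries reconstructed from similarity
feedback. `sscc` implements a two-party protocol in which the client learns
**only the number of database fingerprints whose Tversky similarity to its
query meets a threshold**, and the server learns nothing about the query.
It is aimed at people studying privacy-preserving cheminformatics: it
includes both the protocol itself and attack simulators that quantify what
the thresholding and dummy padding actually buy.

## The score at the core

Fingerprints are length-ℓ bit vectors (ℓ = 166, MACCS-style, by default).
Similarity is the Tversky index

    TI_{α,β}(p, q) = |p ∩ q| / (|p ∩ q| + α|p \ q| + β|q \ p|),

which specializes to Jaccard/Tanimoto (α = β = 1) and Dice (α = β = 1/2).
With rational parameters α = μa/γ, β = μb/γ and threshold θ = θn/θd, the
predicate TI ≥ θ is rescaled into the integer **threshold Tversky score**

    λ1·|p ∩ q| − λ2·|p| − λ3·|q|,

with λ1 = (γ(θd − θn) + θn(μa + μb))/g, λ2 = θn·μa/g, λ3 = θn·μb/g and g
the gcd of those three numerators: the score is non-negative exactly when
TI ≥ θ. Because the score is an affine form in the query bits, the server
can compute its **encryption** from encrypted query bits alone, using an
additively homomorphic cryptosystem (lifted ElGamal over the 192-bit
prime-order curve secp192k1).

Two hardening layers protect the database:

* **Dummy padding** — the server never returns individual scores. It mixes
  the M true encrypted scores with n encrypted dummy values, shuffles, and
  discloses only `s_d`, the number of non-negative dummies. The client
  decrypts, counts non-negatives `s_c`, and learns `s_c − s_d`: the count,
  nothing else.
* **Zero-knowledge bit proofs** — each encrypted query bit carries a
  non-interactive proof (disjunctive Chaum–Pedersen, Fiat–Shamir) that its
  plaintext is 0 or 1, so a malicious client cannot smuggle a huge
  component that would make the score leak a single database bit.

The `security_eval` functions simulate the attacks this design answers: a
score-revealing server loses an ℓ-bit entry to exactly ℓ + 1 queries
(`plain_score_attack`), while a sign-only server leaves an attacker with a
tiny hit probability (`hit_probability`) and dummy padding pushes the
Bayesian guess-the-true-score attack down to its leak-free prior ideal
(`dummy_guess_experiment`).

## Worked example

```r
library(sscc)

params <- tversky_params(mu_a = 1, mu_b = 1, gamma = 1,
                         theta_n = 4, theta_d = 5)   # Jaccard, theta = 4/5
derive_lambdas(params)
#> <lambda_params: (9, 4, 4), g=1>
score_range(166, derive_lambdas(params))
#>  min  max
#> -664  166          # so k = 831 possible score values

db <- random_fingerprints(100, length = 166, density = 0.3, seed = 11)
q  <- db[[37]]                       # query a known entry
res <- run_protocol(q, db, params, dummy_config(n = 1000), seed = 99)
res
#> similar compounds: 1  (s_c = 182, s_d = 181)
count_similar(q, db, params)         # plaintext brute force agrees
#> [1] 1
```

One database entry (the planted one) meets Jaccard ≥ 0.8; the client sees
182 non-negative values among the 1100 shuffled ciphertexts and 181
non-negative dummies, so it learns the count 1 and nothing about which
items were real. The attack simulators show why the server insists on this
shape of reply:

```r
lam <- derive_lambdas(params)
hidden <- db[[1]]
attack <- plain_score_attack(function(qq) threshold_tversky(hidden, qq, lam), 166)
attack$total_queries                 # exact recovery if scores were revealed
#> [1] 167

w <- rand_prior(831, seed = 1)       # synthetic prior over the 831 scores
c(n0     = dummy_guess_experiment(w, 0,     trials = 10000, seed = 2),
  n831   = dummy_guess_experiment(w, 831,   trials = 10000, seed = 2),
  n83100 = dummy_guess_experiment(w, 83100, trials = 10000, seed = 2),
  ideal  = max(w))
#>      n0    n831  n83100   ideal
#> 1.00000 0.00990 0.00460 0.00313
```

With no dummies the true score is handed over (success 1.0); with 100×831
dummies the attacker is within Monte-Carlo noise of the leak-free ideal
`max_i w_i`.

A thin command-line front end is installed as `exec/sscc`
(`keygen`, `fps-gen`, `query`, `respond`, `evaluate`, `simulate`); see the
header of that script for usage.

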