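Package: sscc
Title: Secure Similar Compounds Counter for Private Fingerprint Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-party privacy-preserving similarity search over binary
    molecular fingerprints. A client learns only how many database
    fingerprints meet a Tversky (Jaccard/Dice) similarity threshold against
    its query, while the server never sees the query in the clear. The
    protocol combines additively homomorphic lifted-ElGamal encryption over
    a prime-order elliptic-curve group, non-interactive zero-knowledge
    proofs that each encrypted query component is a bit, and dummy-score
    padding that hides individual similarity scores behind a shuffled
    multiset. Also provides plaintext threshold-Tversky scoring, an
    FPS-style fingerprint reader/writer, a synthetic fingerprint generator,
    and attack simulators quantifying the privacy gained by thresholding
    and dummy padding (regression attacks, hit-probability estimation, and
    Bayesian dummy-guessing experiments).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
SystemRequirements: OpenSSL (libcrypto)
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
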