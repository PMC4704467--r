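// Lifted-ElGamal additively homomorphic encryption over a named prime-order
// elliptic-curve group (OpenSSL libcrypto), plus the disjunctive
// Chaum-Pedersen zero-knowledge bit proof used to validate encrypted query
// bits. All group elements cross the R boundary as hex strings (compressed
// point encoding); scalars as hex strings; plaintexts as R integers.

#include <Rcpp.h>
#include <openssl/ec.h>
#include <openssl/bn.h>
#include <openssl/obj_mac.h>
#include <openssl/objects.h>
#include <openssl/sha.h>
#include <openssl/rand.h>

#include <map>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

// ---- group cache ----------------------------------------------------------

EC_GROUP* get_group(const std::string& name) {
  static std::map<std::string, EC_GROUP*> cache;
  auto it = cache.find(name);
  if (it != cache.end()) return it->second;
  int nid = OBJ_sn2nid(name.c_str());
  if (nid == NID_undef) stop("unknown curve name: '%s'", name.c_str());
  EC_GROUP* g = EC_GROUP_new_by_curve_name(nid);
  if (!g) stop("curve '%s' is not supported by this OpenSSL build", name.c_str());
  cache[name] = g;
  return g;
}

// RAII helpers
struct Bn {
  BIGNUM* p;
  Bn() : p(BN_new()) {}
  explicit Bn(BIGNUM* q) : p(q) {}
  ~Bn() { if (p) BN_free(p); }
  operator BIGNUM*() { return p; }
  Bn(const Bn&) = delete;
  Bn& operator=(const Bn&) = delete;
};

struct Pt {
  EC_POINT* p;
  explicit Pt(const EC_GROUP* g) : p(EC_POINT_new(g)) {}
  ~Pt() { if (p) EC_POINT_free(p); }
  operator EC_POINT*() { return p; }
  Pt(const Pt&) = delete;
  Pt& operator=(const Pt&) = delete;
};

struct Ctx {
  BN_CTX* p;
  Ctx() : p(BN_CTX_new()) {}
  ~Ctx() { if (p) BN_CTX_free(p); }
  operator BN_CTX*() { return p; }
};

void hex2bn(Bn& b, const std::string& hex) {
  BIGNUM* raw = b.p;
  if (BN_hex2bn(&raw, hex.c_str()) == 0)
    stop("malformed scalar hex: '%s'", hex.c_str());
  b.p = raw;
}

std::string bn2hex(const BIGNUM* b) {
  char* s = BN_bn2hex(b);
  std::string out(s);
  OPENSSL_free(s);
  return out;
}

// parse point; returns false on malformed input instead of throwing
bool hex2point(const EC_GROUP* g, const std::string& hex, EC_POINT* out,
               BN_CTX* ctx) {
  if (hex.empty()) return false;
  return EC_POINT_hex2point(g, hex.c_str(), out, ctx) != nullptr;
}

std::string point2hex(const EC_GROUP* g, const EC_POINT* p, BN_CTX* ctx) {
  char* s = EC_POINT_point2hex(g, p, POINT_CONVERSION_COMPRESSED, ctx);
  if (!s) stop("point serialization failed");
  std::string out(s);
  OPENSSL_free(s);
  return out;
}

// scalar from hex reduced into [0, order)
void scalar_mod(const EC_GROUP* g, const std::string& hex, Bn& out,
                BN_CTX* ctx) {
  Bn raw;
  hex2bn(raw, hex);
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  BN_nnmod(out, raw, ord, ctx);
}

// signed integer -> scalar mod order (negative via order - |m|)
void int_scalar(const EC_GROUP* g, double m, Bn& out, BN_CTX* ctx) {
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  bool neg = m < 0;
  double a = neg ? -m : m;
  if (a != std::floor(a) || a > 9e15) stop("plaintext/scalar must be an integer of moderate size");
  Bn mag;
  {
    char buf[32];
    snprintf(buf, sizeof(buf), "%.0f", a);
    BIGNUM* raw = mag.p;
    BN_dec2bn(&raw, buf);
    mag.p = raw;
  }
  BN_nnmod(mag, mag, ord, ctx);
  if (neg && !BN_is_zero(mag)) BN_sub(out, ord, mag);
  else BN_copy(out, mag);
}

// m*G (handles sign through int_scalar)
void mul_base(const EC_GROUP* g, double m, Pt& out, BN_CTX* ctx) {
  Bn s;
  int_scalar(g, m, s, ctx);
  EC_POINT_mul(g, out, s, nullptr, nullptr, ctx);
}

void check_ct(const CharacterMatrix& ct) {
  if (ct.ncol() != 2) stop("ciphertext matrix must have two columns (c1, c2)");
}

std::string sha256_mod_order_hex(const EC_GROUP* g,
                                 const std::string& transcript, BN_CTX* ctx) {
  unsigned char md[SHA256_DIGEST_LENGTH];
  SHA256(reinterpret_cast<const unsigned char*>(transcript.data()),
         transcript.size(), md);
  Bn h;
  BN_bin2bn(md, SHA256_DIGEST_LENGTH, h);
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  BN_nnmod(h, h, ord, ctx);
  return bn2hex(h);
}

}  // namespace

// ---- group information ----------------------------------------------------

// [[Rcpp::export]]
std::string cpp_group_order(std::string curve) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  return bn2hex(ord);
}

// [[Rcpp::export]]
std::string cpp_group_generator(std::string curve) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  return point2hex(g, EC_GROUP_get0_generator(g), ctx);
}

// Cryptographically secure scalars in [1, order-1].
// [[Rcpp::export]]
CharacterVector cpp_rand_scalars(std::string curve, int n) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  CharacterVector out(n);
  Bn one;
  BN_one(one);
  Bn upper;
  BN_sub(upper, ord, one);
  for (int i = 0; i < n; ++i) {
    Bn r;
    if (!BN_rand_range(r, upper)) stop("OpenSSL RNG failure");
    BN_add(r, r, one);  // in [1, order-1]
    out[i] = bn2hex(r);
  }
  return out;
}

// Reduce externally supplied scalar material (e.g. from a seeded test RNG)
// into [1, order-1].
// [[Rcpp::export]]
CharacterVector cpp_scalars_mod_order(std::string curve, CharacterVector hex) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  CharacterVector out(hex.size());
  for (R_xlen_t i = 0; i < hex.size(); ++i) {
    Bn s;
    scalar_mod(g, as<std::string>(hex[i]), s, ctx);
    if (BN_is_zero(s)) BN_one(s);
    out[i] = bn2hex(s);
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_pub_from_sec(std::string curve, std::string sk) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  Bn s;
  scalar_mod(g, sk, s, ctx);
  Pt pub(g);
  EC_POINT_mul(g, pub, s, nullptr, nullptr, ctx);
  return point2hex(g, pub, ctx);
}

// ---- encryption -----------------------------------------------------------

// Enc(m; r) = (r*G, r*PK + m*G)
// [[Rcpp::export]]
CharacterMatrix cpp_encrypt(std::string curve, std::string pk,
                            NumericVector m, CharacterVector r) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  int n = m.size();
  if (r.size() != n) stop("need one randomness scalar per message");
  Pt P(g);
  if (!hex2point(g, pk, P, ctx)) stop("malformed public key");
  CharacterMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    Bn ri;
    scalar_mod(g, as<std::string>(r[i]), ri, ctx);
    Pt c1(g), c2(g), mg(g);
    EC_POINT_mul(g, c1, ri, nullptr, nullptr, ctx);      // r*G
    EC_POINT_mul(g, c2, nullptr, P, ri, ctx);            // r*PK
    mul_base(g, m[i], mg, ctx);                          // m*G
    EC_POINT_add(g, c2, c2, mg, ctx);
    out(i, 0) = point2hex(g, c1, ctx);
    out(i, 1) = point2hex(g, c2, ctx);
  }
  return out;
}

// componentwise homomorphic addition, with single-row recycling
// [[Rcpp::export]]
CharacterMatrix cpp_ct_add(std::string curve, CharacterMatrix a,
                           CharacterMatrix b) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  check_ct(a);
  check_ct(b);
  int n = std::max(a.nrow(), b.nrow());
  if ((a.nrow() != n && a.nrow() != 1) || (b.nrow() != n && b.nrow() != 1))
    stop("incompatible ciphertext counts: %d vs %d", a.nrow(), b.nrow());
  CharacterMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    int ia = a.nrow() == 1 ? 0 : i, ib = b.nrow() == 1 ? 0 : i;
    for (int k = 0; k < 2; ++k) {
      Pt pa(g), pb(g);
      if (!hex2point(g, as<std::string>(a(ia, k)), pa, ctx) ||
          !hex2point(g, as<std::string>(b(ib, k)), pb, ctx))
        stop("malformed ciphertext");
      EC_POINT_add(g, pa, pa, pb, ctx);
      out(i, k) = point2hex(g, pa, ctx);
    }
  }
  return out;
}

// scalar multiple of the plaintext: e ⊗ ct (e may be negative)
// [[Rcpp::export]]
CharacterMatrix cpp_ct_smul(std::string curve, NumericVector e,
                            CharacterMatrix a) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  check_ct(a);
  int n = std::max((int)e.size(), (int)a.nrow());
  if ((a.nrow() != n && a.nrow() != 1) || (e.size() != n && e.size() != 1))
    stop("incompatible lengths in scalar multiplication");
  CharacterMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    int ie = e.size() == 1 ? 0 : i, ia = a.nrow() == 1 ? 0 : i;
    Bn s;
    int_scalar(g, e[ie], s, ctx);
    for (int k = 0; k < 2; ++k) {
      Pt p(g);
      if (!hex2point(g, as<std::string>(a(ia, k)), p, ctx))
        stop("malformed ciphertext");
      EC_POINT_mul(g, p, nullptr, p, s, ctx);
      out(i, k) = point2hex(g, p, ctx);
    }
  }
  return out;
}

// homomorphic sum of all rows -> single ciphertext
// [[Rcpp::export]]
CharacterMatrix cpp_ct_sum(std::string curve, CharacterMatrix a) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  check_ct(a);
  CharacterMatrix out(1, 2);
  for (int k = 0; k < 2; ++k) {
    Pt acc(g);
    EC_POINT_set_to_infinity(g, acc);
    for (int i = 0; i < a.nrow(); ++i) {
      Pt p(g);
      if (!hex2point(g, as<std::string>(a(i, k)), p, ctx))
        stop("malformed ciphertext");
      EC_POINT_add(g, acc, acc, p, ctx);
    }
    out(0, k) = point2hex(g, acc, ctx);
  }
  return out;
}

// re-encryption with fresh randomness: ct ⊕ Enc(0; r)
// [[Rcpp::export]]
CharacterMatrix cpp_rerandomize(std::string curve, std::string pk,
                                CharacterMatrix a, CharacterVector r) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  check_ct(a);
  if (r.size() != a.nrow()) stop("need one scalar per ciphertext");
  Pt P(g);
  if (!hex2point(g, pk, P, ctx)) stop("malformed public key");
  CharacterMatrix out(a.nrow(), 2);
  for (int i = 0; i < a.nrow(); ++i) {
    Bn ri;
    scalar_mod(g, as<std::string>(r[i]), ri, ctx);
    Pt c1(g), c2(g), t(g);
    if (!hex2point(g, as<std::string>(a(i, 0)), c1, ctx) ||
        !hex2point(g, as<std::string>(a(i, 1)), c2, ctx))
      stop("malformed ciphertext");
    EC_POINT_mul(g, t, ri, nullptr, nullptr, ctx);
    EC_POINT_add(g, c1, c1, t, ctx);
    EC_POINT_mul(g, t, nullptr, P, ri, ctx);
    EC_POINT_add(g, c2, c2, t, ctx);
    out(i, 0) = point2hex(g, c1, ctx);
    out(i, 1) = point2hex(g, c2, ctx);
  }
  return out;
}

// ---- decryption via small-range discrete-log table -------------------------

// Decode m in [lo, hi]; NA_INTEGER marks a plaintext outside the range.
// [[Rcpp::export]]
IntegerVector cpp_decrypt(std::string curve, std::string sk, CharacterMatrix a,
                          int lo, int hi) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  check_ct(a);
  if (lo > hi) stop("empty plaintext range");
  if ((double)hi - (double)lo > (double)(1 << 24))
    stop("plaintext range too wide for table decoding");
  Bn s;
  scalar_mod(g, sk, s, ctx);
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  Bn negs;
  BN_sub(negs, ord, s);  // -sk mod order

  // table of m*G for m in [lo, hi], keyed by compressed octets
  std::unordered_map<std::string, int> table;
  table.reserve((size_t)(hi - lo + 1) * 2);
  Pt cur(g), G(g);
  EC_POINT_copy(G, EC_GROUP_get0_generator(g));
  mul_base(g, lo, cur, ctx);
  std::vector<unsigned char> buf(128);
  for (int m = lo; m <= hi; ++m) {
    size_t len = EC_POINT_point2oct(g, cur, POINT_CONVERSION_COMPRESSED,
                                    buf.data(), buf.size(), ctx);
    table.emplace(std::string((char*)buf.data(), len), m);
    if (m < hi) EC_POINT_add(g, cur, cur, G, ctx);
  }

  IntegerVector out(a.nrow());
  for (int i = 0; i < a.nrow(); ++i) {
    Pt c1(g), c2(g);
    if (!hex2point(g, as<std::string>(a(i, 0)), c1, ctx) ||
        !hex2point(g, as<std::string>(a(i, 1)), c2, ctx))
      stop("malformed ciphertext");
    Pt M(g);
    EC_POINT_mul(g, M, nullptr, c1, negs, ctx);  // -sk * c1
    EC_POINT_add(g, M, M, c2, ctx);              // c2 - sk*c1 = m*G
    size_t len = EC_POINT_point2oct(g, M, POINT_CONVERSION_COMPRESSED,
                                    buf.data(), buf.size(), ctx);
    auto it = table.find(std::string((char*)buf.data(), len));
    out[i] = (it == table.end()) ? NA_INTEGER : it->second;
  }
  return out;
}

// ---- encrypted threshold-Tversky scoring -----------------------------------

// For each database fingerprint p^(j): t_j = λ1 ⊗ Enc(|p∩q|)
//   ⊕ λ2 ⊗ Enc(−|p^(j)|) ⊕ λ3 ⊗ Enc(−|q|), then rerandomized.
// Enc(|p∩q|) is the homomorphic sum of the query-bit ciphertexts selected by
// p^(j); Enc(−|q|) is (−1) ⊗ the sum of all query-bit ciphertexts — the
// server derives it itself and never asks the client for it.
// [[Rcpp::export]]
CharacterMatrix cpp_scores(std::string curve, std::string pk,
                           CharacterMatrix qct, IntegerMatrix db,
                           NumericVector lam, CharacterVector r_enc,
                           CharacterVector r_rand) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  check_ct(qct);
  int L = qct.nrow(), M = db.nrow();
  if (db.ncol() != L) stop("database fingerprint length != query length");
  if (lam.size() != 3) stop("lam must be (lambda1, lambda2, lambda3)");
  if (r_enc.size() != M || r_rand.size() != M)
    stop("need one encryption and one rerandomization scalar per entry");
  Pt P(g);
  if (!hex2point(g, pk, P, ctx)) stop("malformed public key");

  // parse query ciphertexts once
  std::vector<EC_POINT*> q1(L), q2(L);
  for (int i = 0; i < L; ++i) {
    q1[i] = EC_POINT_new(g);
    q2[i] = EC_POINT_new(g);
    if (!hex2point(g, as<std::string>(qct(i, 0)), q1[i], ctx) ||
        !hex2point(g, as<std::string>(qct(i, 1)), q2[i], ctx)) {
      for (int k = 0; k <= i; ++k) { EC_POINT_free(q1[k]); EC_POINT_free(q2[k]); }
      stop("malformed query ciphertext at position %d", i + 1);
    }
  }

  // Enc(-|q|) = (-1) ⊗ Σ Enc(q_i)
  Pt sum1(g), sum2(g);
  EC_POINT_set_to_infinity(g, sum1);
  EC_POINT_set_to_infinity(g, sum2);
  for (int i = 0; i < L; ++i) {
    EC_POINT_add(g, sum1, sum1, q1[i], ctx);
    EC_POINT_add(g, sum2, sum2, q2[i], ctx);
  }
  Pt nq1(g), nq2(g);
  EC_POINT_copy(nq1, sum1);
  EC_POINT_copy(nq2, sum2);
  EC_POINT_invert(g, nq1, ctx);
  EC_POINT_invert(g, nq2, ctx);

  Bn l1, l3;
  int_scalar(g, lam[0], l1, ctx);
  int_scalar(g, lam[2], l3, ctx);
  // λ3 ⊗ Enc(−|q|), shared across entries
  Pt e3a(g), e3b(g);
  EC_POINT_mul(g, e3a, nullptr, nq1, l3, ctx);
  EC_POINT_mul(g, e3b, nullptr, nq2, l3, ctx);

  CharacterMatrix out(M, 2);
  for (int j = 0; j < M; ++j) {
    // Enc(|p∩q|): sum query ciphertexts at positions where p bit is 1
    Pt c1(g), c2(g);
    EC_POINT_set_to_infinity(g, c1);
    EC_POINT_set_to_infinity(g, c2);
    int pop = 0;
    for (int i = 0; i < L; ++i) {
      if (db(j, i) == 1) {
        ++pop;
        EC_POINT_add(g, c1, c1, q1[i], ctx);
        EC_POINT_add(g, c2, c2, q2[i], ctx);
      }
    }
    // λ1 ⊗ c
    EC_POINT_mul(g, c1, nullptr, c1, l1, ctx);
    EC_POINT_mul(g, c2, nullptr, c2, l1, ctx);
    // ⊕ λ2 ⊗ Enc(−|p^(j)|): encrypt −λ2·pop fresh (same plaintext, one mul)
    {
      Bn rj;
      scalar_mod(g, as<std::string>(r_enc[j]), rj, ctx);
      Pt e1(g), e2(g), mg(g);
      EC_POINT_mul(g, e1, rj, nullptr, nullptr, ctx);
      EC_POINT_mul(g, e2, nullptr, P, rj, ctx);
      mul_base(g, -(double)lam[1] * pop, mg, ctx);
      EC_POINT_add(g, e2, e2, mg, ctx);
      EC_POINT_add(g, c1, c1, e1, ctx);
      EC_POINT_add(g, c2, c2, e2, ctx);
    }
    // ⊕ λ3 ⊗ Enc(−|q|)
    EC_POINT_add(g, c1, c1, e3a, ctx);
    EC_POINT_add(g, c2, c2, e3b, ctx);
    // rerandomize before release
    {
      Bn rj;
      scalar_mod(g, as<std::string>(r_rand[j]), rj, ctx);
      Pt t(g);
      EC_POINT_mul(g, t, rj, nullptr, nullptr, ctx);
      EC_POINT_add(g, c1, c1, t, ctx);
      EC_POINT_mul(g, t, nullptr, P, rj, ctx);
      EC_POINT_add(g, c2, c2, t, ctx);
    }
    out(j, 0) = point2hex(g, c1, ctx);
    out(j, 1) = point2hex(g, c2, ctx);
  }
  for (int i = 0; i < L; ++i) { EC_POINT_free(q1[i]); EC_POINT_free(q2[i]); }
  return out;
}

// ---- zero-knowledge bit proof ----------------------------------------------

// Disjunctive Chaum-Pedersen proof that ct = (C1, C2) encrypts 0 or 1 under
// pk, made non-interactive with a Fiat-Shamir challenge over SHA-256.
//   branch 0: ∃r  C1 = r·G, C2     = r·PK
//   branch 1: ∃r  C1 = r·G, C2 − G = r·PK
// Proof fields: A0, B0, A1, B1 (commitments), e0, e1, z0, z1 (scalars);
// e0 + e1 must equal H(transcript) mod order.

namespace {

std::string fs_challenge(const EC_GROUP* g, const std::string& curve,
                         const std::string& pk, const std::string& c1,
                         const std::string& c2, const std::string& a0,
                         const std::string& b0, const std::string& a1,
                         const std::string& b1, BN_CTX* ctx) {
  std::string t = "sscc-bitproof-v1|" + curve + "|" + pk + "|" + c1 + "|" +
                  c2 + "|" + a0 + "|" + b0 + "|" + a1 + "|" + b1;
  return sha256_mod_order_hex(g, t, ctx);
}

void rand_scalar(const EC_GROUP* g, Bn& out, BN_CTX* ctx) {
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  if (!BN_rand_range(out, ord)) stop("OpenSSL RNG failure");
}

}  // namespace

// The honest prover. m is the claimed plaintext bit; the real branch is
// chosen as (m != 0), so forcing it through with m ∉ {0,1} produces a proof
// that verification rejects (soundness is exercised by tests this way).
// [[Rcpp::export]]
CharacterMatrix cpp_prove_bits(std::string curve, std::string pk,
                               IntegerVector m, CharacterVector r,
                               CharacterMatrix ct) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  check_ct(ct);
  int n = m.size();
  if (r.size() != n || ct.nrow() != n)
    stop("m, r and ct must have one entry per bit");
  Pt P(g);
  if (!hex2point(g, pk, P, ctx)) stop("malformed public key");
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  Pt G(g);
  EC_POINT_copy(G, EC_GROUP_get0_generator(g));

  CharacterMatrix out(n, 8);
  colnames(out) = CharacterVector::create("A0", "B0", "A1", "B1", "e0", "e1",
                                          "z0", "z1");
  for (int i = 0; i < n; ++i) {
    Bn ri;
    scalar_mod(g, as<std::string>(r[i]), ri, ctx);
    Pt C1(g), C2(g);
    if (!hex2point(g, as<std::string>(ct(i, 0)), C1, ctx) ||
        !hex2point(g, as<std::string>(ct(i, 1)), C2, ctx))
      stop("malformed ciphertext");
    // Y_b: branch-0 target C2, branch-1 target C2 - G
    Pt Y0(g), Y1(g), negG(g);
    EC_POINT_copy(Y0, C2);
    EC_POINT_copy(negG, G);
    EC_POINT_invert(g, negG, ctx);
    EC_POINT_add(g, Y1, C2, negG, ctx);

    int real_b = (m[i] != 0) ? 1 : 0;
    EC_POINT* Yreal = real_b == 0 ? (EC_POINT*)Y0 : (EC_POINT*)Y1;
    EC_POINT* Yfake = real_b == 0 ? (EC_POINT*)Y1 : (EC_POINT*)Y0;

    // simulate the fake branch: random e_f, z_f; A_f = z_f·G − e_f·C1,
    // B_f = z_f·PK − e_f·Y_f
    Bn ef, zf;
    rand_scalar(g, ef, ctx);
    rand_scalar(g, zf, ctx);
    Pt Af(g), Bf(g), t1(g), t2(g);
    Bn nef;
    BN_sub(nef, ord, ef);
    EC_POINT_mul(g, t1, zf, nullptr, nullptr, ctx);        // z_f·G
    EC_POINT_mul(g, t2, nullptr, C1, nef, ctx);            // −e_f·C1
    EC_POINT_add(g, Af, t1, t2, ctx);
    EC_POINT_mul(g, t1, nullptr, P, zf, ctx);              // z_f·PK
    EC_POINT_mul(g, t2, nullptr, Yfake, nef, ctx);         // −e_f·Y_f
    EC_POINT_add(g, Bf, t1, t2, ctx);

    // commit on the real branch
    Bn rho;
    rand_scalar(g, rho, ctx);
    Pt Ar(g), Br(g);
    EC_POINT_mul(g, Ar, rho, nullptr, nullptr, ctx);       // ρ·G
    EC_POINT_mul(g, Br, nullptr, P, rho, ctx);             // ρ·PK
    (void)Yreal;  // the real-branch commitment does not involve Y

    std::string hA0, hB0, hA1, hB1;
    if (real_b == 0) {
      hA0 = point2hex(g, Ar, ctx); hB0 = point2hex(g, Br, ctx);
      hA1 = point2hex(g, Af, ctx); hB1 = point2hex(g, Bf, ctx);
    } else {
      hA0 = point2hex(g, Af, ctx); hB0 = point2hex(g, Bf, ctx);
      hA1 = point2hex(g, Ar, ctx); hB1 = point2hex(g, Br, ctx);
    }
    std::string e_hex =
        fs_challenge(g, curve, pk, as<std::string>(ct(i, 0)),
                     as<std::string>(ct(i, 1)), hA0, hB0, hA1, hB1, ctx);
    Bn e;
    hex2bn(e, e_hex);
    Bn er;  // e_real = e − e_fake mod order
    BN_mod_sub(er, e, ef, ord, ctx);
    Bn zr;  // z_real = ρ + e_real·r mod order
    BN_mod_mul(zr, er, ri, ord, ctx);
    BN_mod_add(zr, zr, rho, ord, ctx);

    out(i, 0) = hA0; out(i, 1) = hB0; out(i, 2) = hA1; out(i, 3) = hB1;
    if (real_b == 0) {
      out(i, 4) = bn2hex(er); out(i, 5) = bn2hex(ef);
      out(i, 6) = bn2hex(zr); out(i, 7) = bn2hex(zf);
    } else {
      out(i, 4) = bn2hex(ef); out(i, 5) = bn2hex(er);
      out(i, 6) = bn2hex(zf); out(i, 7) = bn2hex(zr);
    }
  }
  return out;
}

// Special-honest-verifier simulator for the interactive sigma protocol:
// given only (pk, ct) and a random total challenge e, fabricates an
// accepting transcript for both branches without knowing the plaintext or
// randomness. Returns the 8 proof fields plus the challenge e used.
// [[Rcpp::export]]
CharacterMatrix cpp_simulate_bits(std::string curve, std::string pk,
                                  CharacterMatrix ct) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  check_ct(ct);
  Pt P(g);
  if (!hex2point(g, pk, P, ctx)) stop("malformed public key");
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  Pt G(g);
  EC_POINT_copy(G, EC_GROUP_get0_generator(g));
  int n = ct.nrow();
  CharacterMatrix out(n, 9);
  colnames(out) = CharacterVector::create("A0", "B0", "A1", "B1", "e0", "e1",
                                          "z0", "z1", "e");
  for (int i = 0; i < n; ++i) {
    Pt C1(g), C2(g);
    if (!hex2point(g, as<std::string>(ct(i, 0)), C1, ctx) ||
        !hex2point(g, as<std::string>(ct(i, 1)), C2, ctx))
      stop("malformed ciphertext");
    Pt Y0(g), Y1(g), negG(g);
    EC_POINT_copy(Y0, C2);
    EC_POINT_copy(negG, G);
    EC_POINT_invert(g, negG, ctx);
    EC_POINT_add(g, Y1, C2, negG, ctx);

    Bn e, e0, e1;
    rand_scalar(g, e, ctx);
    rand_scalar(g, e0, ctx);
    BN_mod_sub(e1, e, e0, ord, ctx);
    std::string hex[4];
    Bn z0, z1;
    for (int b = 0; b < 2; ++b) {
      BIGNUM* eb = (b == 0) ? (BIGNUM*)e0 : (BIGNUM*)e1;
      Bn& zb = (b == 0) ? z0 : z1;
      EC_POINT* Yb = (b == 0) ? (EC_POINT*)Y0 : (EC_POINT*)Y1;
      rand_scalar(g, zb, ctx);
      Bn neb;
      BN_sub(neb, ord, eb);
      Pt A(g), B(g), t1(g), t2(g);
      EC_POINT_mul(g, t1, zb, nullptr, nullptr, ctx);
      EC_POINT_mul(g, t2, nullptr, C1, neb, ctx);
      EC_POINT_add(g, A, t1, t2, ctx);
      EC_POINT_mul(g, t1, nullptr, P, zb, ctx);
      EC_POINT_mul(g, t2, nullptr, Yb, neb, ctx);
      EC_POINT_add(g, B, t1, t2, ctx);
      hex[2 * b] = point2hex(g, A, ctx);
      hex[2 * b + 1] = point2hex(g, B, ctx);
    }
    out(i, 0) = hex[0]; out(i, 1) = hex[1];
    out(i, 2) = hex[2]; out(i, 3) = hex[3];
    out(i, 4) = bn2hex(e0); out(i, 5) = bn2hex(e1);
    out(i, 6) = bn2hex(z0); out(i, 7) = bn2hex(z1);
    out(i, 8) = bn2hex(e);
  }
  return out;
}

// Verifier. With `challenge` empty the total challenge is recomputed by
// Fiat-Shamir from the transcript (the non-interactive proof); a supplied
// challenge instead checks the interactive sigma-protocol equations against
// that value (used to validate simulated transcripts).
// [[Rcpp::export]]
LogicalVector cpp_verify_bits(std::string curve, std::string pk,
                              CharacterMatrix ct, CharacterMatrix proof,
                              CharacterVector challenge =
                                  CharacterVector::create()) {
  EC_GROUP* g = get_group(curve);
  Ctx ctx;
  check_ct(ct);
  if (proof.ncol() != 8) stop("proof matrix must have 8 columns");
  if (proof.nrow() != ct.nrow()) stop("one proof per ciphertext required");
  Bn ord;
  EC_GROUP_get_order(g, ord, ctx);
  Pt P(g);
  if (!hex2point(g, pk, P, ctx)) stop("malformed public key");
  Pt G(g);
  EC_POINT_copy(G, EC_GROUP_get0_generator(g));

  LogicalVector out(ct.nrow());
  for (int i = 0; i < ct.nrow(); ++i) {
    out[i] = false;
    Pt C1(g), C2(g), A0(g), B0(g), A1(g), B1(g);
    if (!hex2point(g, as<std::string>(ct(i, 0)), C1, ctx)) continue;
    if (!hex2point(g, as<std::string>(ct(i, 1)), C2, ctx)) continue;
    if (!hex2point(g, as<std::string>(proof(i, 0)), A0, ctx)) continue;
    if (!hex2point(g, as<std::string>(proof(i, 1)), B0, ctx)) continue;
    if (!hex2point(g, as<std::string>(proof(i, 2)), A1, ctx)) continue;
    if (!hex2point(g, as<std::string>(proof(i, 3)), B1, ctx)) continue;
    Bn e0, e1, z0, z1;
    try {
      hex2bn(e0, as<std::string>(proof(i, 4)));
      hex2bn(e1, as<std::string>(proof(i, 5)));
      hex2bn(z0, as<std::string>(proof(i, 6)));
      hex2bn(z1, as<std::string>(proof(i, 7)));
    } catch (...) {
      continue;
    }
    // challenge consistency
    std::string e_hex;
    if (challenge.size() == 0) {
      e_hex = fs_challenge(
          g, curve, pk, as<std::string>(ct(i, 0)), as<std::string>(ct(i, 1)),
          as<std::string>(proof(i, 0)), as<std::string>(proof(i, 1)),
          as<std::string>(proof(i, 2)), as<std::string>(proof(i, 3)), ctx);
    } else {
      e_hex = as<std::string>(challenge[challenge.size() == 1 ? 0 : i]);
    }
    Bn e, esum;
    hex2bn(e, e_hex);
    BN_mod_add(esum, e0, e1, ord, ctx);
    if (BN_cmp(e, esum) != 0) continue;

    // targets
    Pt Y0(g), Y1(g), negG(g);
    EC_POINT_copy(Y0, C2);
    EC_POINT_copy(negG, G);
    EC_POINT_invert(g, negG, ctx);
    EC_POINT_add(g, Y1, C2, negG, ctx);

    bool ok = true;
    // branch b: z_b·G == A_b + e_b·C1  and  z_b·PK == B_b + e_b·Y_b
    for (int b = 0; b < 2 && ok; ++b) {
      BIGNUM* eb = (b == 0) ? (BIGNUM*)e0 : (BIGNUM*)e1;
      BIGNUM* zb = (b == 0) ? (BIGNUM*)z0 : (BIGNUM*)z1;
      EC_POINT* Ab = (b == 0) ? (EC_POINT*)A0 : (EC_POINT*)A1;
      EC_POINT* Bb = (b == 0) ? (EC_POINT*)B0 : (EC_POINT*)B1;
      EC_POINT* Yb = (b == 0) ? (EC_POINT*)Y0 : (EC_POINT*)Y1;
      Pt lhs(g), rhs(g), t(g);
      EC_POINT_mul(g, lhs, zb, nullptr, nullptr, ctx);
      EC_POINT_mul(g, t, nullptr, C1, eb, ctx);
      EC_POINT_add(g, rhs, Ab, t, ctx);
      if (EC_POINT_cmp(g, lhs, rhs, ctx) != 0) { ok = false; break; }
      EC_POINT_mul(g, lhs, nullptr, P, zb, ctx);
      EC_POINT_mul(g, t, nullptr, Yb, eb, ctx);
      EC_POINT_add(g, rhs, Bb, t, ctx);
      if (EC_POINT_cmp(g, lhs, rhs, ctx) != 0) { ok = false; break; }
    }
    out[i] = ok;
  }
  return out;
}
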