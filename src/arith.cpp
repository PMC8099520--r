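// Adaptive binary arithmetic coder (order-0).
//
// Bit-exact contract (sender and receiver must agree):
//   * 32-bit low/high registers, initialised to 0x00000000 / 0xFFFFFFFF.
//   * Adaptive model: counts c0 = c1 = 1 before the first symbol; the count of
//     the coded symbol is incremented *after* coding it; when c0 + c1 reaches
//     2^24 both counts are halved (floor, kept >= 1).
//   * Split point: mid = low + floor(range * c0 / (c0 + c1)) - 1 is the last
//     code value of the "0" region; range = high - low + 1.
//   * Renormalisation emits the shared top bit; E3 underflow (low >= 1/4,
//     high < 3/4) is handled with pending-bit carry propagation.
//   * Flush: one disambiguating bit (plus pending bits) chosen from low.
//   * Bits are packed MSB-first into bytes; the final byte is zero padded.
// The decoder mirrors the model exactly and may consume up to 32 zero bits
// past the end of the byte stream (the encoder's flush margin); needing more
// than that is reported as reading past the end of the stream.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const uint64_t CODE_MAX = 0xFFFFFFFFULL;
const uint64_t HALF     = 0x80000000ULL;
const uint64_t QUARTER  = 0x40000000ULL;
const uint64_t THREE_Q  = 0xC0000000ULL;
const uint64_t COUNT_CAP = 1ULL << 24;

struct BitWriter {
  std::vector<uint8_t> bytes;
  int nbits = 0;
  void push(int bit) {
    if (nbits % 8 == 0) bytes.push_back(0);
    if (bit) bytes.back() |= static_cast<uint8_t>(0x80u >> (nbits % 8));
    ++nbits;
  }
};

struct BitReader {
  const uint8_t* data;
  size_t nbytes;
  size_t pos = 0;      // bit position
  size_t overrun = 0;  // zero bits consumed past the end
  explicit BitReader(const uint8_t* d, size_t n) : data(d), nbytes(n) {}
  int next() {
    if (pos >= 8 * nbytes) {
      if (++overrun > 32)
        stop("arithmetic decoder read past the end of the stream");
      return 0;
    }
    int bit = (data[pos / 8] >> (7 - pos % 8)) & 1;
    ++pos;
    return bit;
  }
};

inline void model_update(uint64_t& c0, uint64_t& c1, int bit) {
  if (bit) ++c1; else ++c0;
  if (c0 + c1 >= COUNT_CAP) {
    c0 = (c0 >> 1) ? (c0 >> 1) : 1;
    c1 = (c1 >> 1) ? (c1 >> 1) : 1;
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_arith_encode")]]
RawVector cpp_arith_encode(IntegerVector bits) {
  uint64_t low = 0, high = CODE_MAX, c0 = 1, c1 = 1;
  long pending = 0;
  BitWriter out;
  const R_xlen_t n = bits.size();
  if (n == 0) return RawVector(0);

  for (R_xlen_t i = 0; i < n; ++i) {
    int bit = bits[i];
    if (bit != 0 && bit != 1) stop("arith_encode: input must be 0/1");
    uint64_t range = high - low + 1;
    uint64_t mid = low + (range * c0) / (c0 + c1) - 1;
    if (bit == 0) high = mid; else low = mid + 1;
    model_update(c0, c1, bit);
    for (;;) {
      if (high < HALF) {
        out.push(0);
        for (; pending > 0; --pending) out.push(1);
      } else if (low >= HALF) {
        out.push(1);
        for (; pending > 0; --pending) out.push(0);
        low -= HALF; high -= HALF;
      } else if (low >= QUARTER && high < THREE_Q) {
        ++pending;
        low -= QUARTER; high -= QUARTER;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
    }
  }
  // flush: disambiguate the final interval
  ++pending;
  if (low < QUARTER) {
    out.push(0);
    for (; pending > 0; --pending) out.push(1);
  } else {
    out.push(1);
    for (; pending > 0; --pending) out.push(0);
  }
  RawVector res(out.bytes.size());
  std::copy(out.bytes.begin(), out.bytes.end(), res.begin());
  return res;
}

// [[Rcpp::export(name = ".cpp_arith_decode")]]
IntegerVector cpp_arith_decode(RawVector bytes, int n_bits) {
  if (n_bits < 0) stop("arith_decode: n_bits must be >= 0");
  IntegerVector out(n_bits);
  if (n_bits == 0) return out;

  BitReader in(RAW(bytes), bytes.size());
  uint64_t low = 0, high = CODE_MAX, c0 = 1, c1 = 1, value = 0;
  for (int i = 0; i < 32; ++i) value = (value << 1) | in.next();

  for (int i = 0; i < n_bits; ++i) {
    uint64_t range = high - low + 1;
    uint64_t mid = low + (range * c0) / (c0 + c1) - 1;
    int bit = value > mid ? 1 : 0;
    if (bit == 0) high = mid; else low = mid + 1;
    model_update(c0, c1, bit);
    out[i] = bit;
    for (;;) {
      if (high < HALF) {
        // nothing
      } else if (low >= HALF) {
        low -= HALF; high -= HALF; value -= HALF;
      } else if (low >= QUARTER && high < THREE_Q) {
        low -= QUARTER; high -= QUARTER; value -= QUARTER;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
      value = (value << 1) | in.next();
    }
  }
  return out;
}

// Pack a 0/1 integer vector MSB-first into raw bytes (zero padded) and back.
// Used for the recovery-sequence payload of the residual codec container.

// [[Rcpp::export(name = ".cpp_pack_bits")]]
RawVector cpp_pack_bits(IntegerVector bits) {
  const R_xlen_t n = bits.size();
  RawVector out((n + 7) / 8);
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = bits[i];
    if (b != 0 && b != 1) stop("pack_bits: input must be 0/1");
    if (b) out[i / 8] |= static_cast<Rbyte>(0x80u >> (i % 8));
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_unpack_bits")]]
IntegerVector cpp_unpack_bits(RawVector bytes, int n_bits) {
  if (n_bits < 0) stop("unpack_bits: n_bits must be >= 0");
  if (static_cast<size_t>(n_bits) > 8 * static_cast<size_t>(bytes.size()))
    stop("unpack_bits: payload is shorter than the declared bit length");
  IntegerVector out(n_bits);
  for (int i = 0; i < n_bits; ++i)
    out[i] = (bytes[i / 8] >> (7 - i % 8)) & 1;
  return out;
}
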