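// Bit-exact block codec for the smart-glove recording format.
//
// Wire grammar (prefix-free descriptors, most frequent symbol shortest):
//   0      DD   8-bit signed delta between consecutive PPG samples
//   10     GB   garbage marker, no payload (artifact; sample counter advances)
//   110    AV   18-bit unsigned absolute PPG value
//   1110   SF   3-bit scale code, immediately followed by a BARE 8-bit signed
//               quotient (no DD descriptor); decoded value = prev + scale * q,
//               scale = 2^(code + 1) in {2,4,...,256}
//   11110  SPO2 6-bit offset-coded saturation (percent - 37, clamped to [0,63])
//   111110 MOVE 16-bit unsigned per-epoch movement count
//
// Block geometry: 25 rows of 157 bytes. Row 1 = [4 B sample counter,
// LSB-first][2 B useful-bit count, LSB-first][151 B payload]; rows 2-25 =
// [2 B useful-bit count][155 B payload]. Serialized block = 3925 bytes,
// zero-padded to 4096 (one flash block). Bits are written MSB-first within
// the payload. Tokens never straddle a row boundary; a row is closed (its
// useful-bit count recorded, trailing bits zero) when the next token does
// not fit. The first data token of every block is an AV, and SpO2/movement
// tokens never migrate across a block boundary, so a new block is opened
// early when a PPG sample's token group would not fit in the current one.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const int ROWS = 25;
const int ROW_BYTES = 157;
const int BLOCK_BYTES = 4096;
const int ROW1_PAYLOAD_BITS = 151 * 8;
const int ROWN_PAYLOAD_BITS = 155 * 8;
const int PPG_MAX = (1 << 18) - 1;

inline int row_capacity(int row) {
  return row == 0 ? ROW1_PAYLOAD_BITS : ROWN_PAYLOAD_BITS;
}

struct Token {
  uint32_t bits;  // descriptor + payload, right-aligned
  int nbits;
};

inline Token tok_av(uint32_t v) {
  return Token{(uint32_t(0x6) << 18) | (v & 0x3FFFFu), 21};
}
inline Token tok_dd(int d) {
  return Token{(uint32_t(0x0) << 8) | (uint32_t(d) & 0xFFu), 9};
}
inline Token tok_gb() { return Token{0x2u, 2}; }
inline Token tok_sf(int code, int q) {
  return Token{(uint32_t(0xE) << 11) | ((uint32_t(code) & 0x7u) << 8) |
                   (uint32_t(q) & 0xFFu),
               15};
}
inline Token tok_spo2(int v) {
  return Token{(uint32_t(0x1E) << 6) | (uint32_t(v) & 0x3Fu), 11};
}
inline Token tok_move(int v) {
  return Token{(uint32_t(0x3E) << 16) | (uint32_t(v) & 0xFFFFu), 22};
}

struct BlockBuilder {
  uint32_t counter;
  std::vector<uint8_t> payload;       // ROWS * row payload bytes, zeroed
  std::vector<uint16_t> useful_bits;  // per row
  int row;
  int bitpos;  // bits already written in current row
  bool open;

  BlockBuilder() : open(false) {}

  void start(uint32_t ctr) {
    counter = ctr;
    payload.assign(151 + 155 * (ROWS - 1), 0);
    useful_bits.assign(ROWS, 0);
    row = 0;
    bitpos = 0;
    open = true;
  }

  int row_payload_offset(int r) const { return r == 0 ? 0 : 151 + 155 * (r - 1); }

  // can the token sequence be packed into what remains of this block?
  bool fits(const std::vector<Token>& toks) const {
    int r = row, bp = bitpos;
    for (const Token& t : toks) {
      if (bp + t.nbits > row_capacity(r)) {
        ++r;
        bp = 0;
        if (r >= ROWS) return false;
        if (t.nbits > row_capacity(r)) return false;
      }
      bp += t.nbits;
    }
    return true;
  }

  void write(const Token& t) {
    if (bitpos + t.nbits > row_capacity(row)) {
      useful_bits[row] = static_cast<uint16_t>(bitpos);
      ++row;
      bitpos = 0;
    }
    int base = row_payload_offset(row) * 8 + bitpos;
    for (int b = t.nbits - 1; b >= 0; --b) {
      if ((t.bits >> b) & 1u) {
        int pos = base + (t.nbits - 1 - b);
        payload[pos >> 3] |= uint8_t(0x80u >> (pos & 7));
      }
    }
    bitpos += t.nbits;
  }

  RawVector finish() {
    useful_bits[row] = static_cast<uint16_t>(bitpos);
    RawVector out(BLOCK_BYTES);  // zero-initialised
    int o = 0;
    for (int r = 0; r < ROWS; ++r) {
      if (r == 0) {
        out[o++] = counter & 0xFF;
        out[o++] = (counter >> 8) & 0xFF;
        out[o++] = (counter >> 16) & 0xFF;
        out[o++] = (counter >> 24) & 0xFF;
      }
      out[o++] = useful_bits[r] & 0xFF;
      out[o++] = (useful_bits[r] >> 8) & 0xFF;
      int nb = (r == 0) ? 151 : 155;
      int off = row_payload_offset(r);
      for (int k = 0; k < nb; ++k) out[o++] = payload[off + k];
    }
    open = false;
    return out;
  }
};

}  // namespace

// Encode a sample stream into 4096-byte blocks.
// ppg: PPG samples; NA or out-of-18-bit-range values are artifacts (GB).
// spo2_idx / move_idx: 0-based index of the PPG sample each auxiliary value
// is bound to (emitted immediately after that sample's token).
// [[Rcpp::export]]
List cpp_encode_stream(IntegerVector ppg, IntegerVector spo2_idx,
                       IntegerVector spo2_code, IntegerVector move_idx,
                       IntegerVector move_val) {
  int n = ppg.size();
  if (n == 0) stop("empty PPG channel");
  std::vector<RawVector> blocks;
  std::vector<double> counters;
  BlockBuilder bb;
  int si = 0, mi = 0;  // cursors into aux channels (assumed sorted by idx)
  int prev = 0;
  bool force_av = true;

  for (int i = 0; i < n; ++i) {
    bool artifact = IntegerVector::is_na(ppg[i]) || ppg[i] < 0 || ppg[i] > PPG_MAX;
    int v = artifact ? 0 : ppg[i];

    std::vector<Token> group;
    auto ppg_token = [&](bool at_block_start) -> Token {
      if (artifact) return tok_gb();
      if (force_av || at_block_start) return tok_av(uint32_t(v));
      long d = long(v) - long(prev);
      if (d >= -128 && d <= 127) return tok_dd(int(d));
      for (int c = 0; c < 8; ++c) {
        long s = 1L << (c + 1);
        if (d % s == 0) {
          long q = d / s;
          if (q >= -128 && q <= 127) return tok_sf(c, int(q));
        }
      }
      return tok_av(uint32_t(v));
    };

    group.push_back(ppg_token(false));
    while (si < spo2_idx.size() && spo2_idx[si] == i) {
      group.push_back(tok_spo2(spo2_code[si]));
      ++si;
    }
    while (mi < move_idx.size() && move_idx[mi] == i) {
      group.push_back(tok_move(move_val[mi]));
      ++mi;
    }

    if (!bb.open || !bb.fits(group)) {
      if (bb.open) {
        blocks.push_back(bb.finish());
      }
      bb.start(uint32_t(i));
      counters.push_back(double(i));
      group[0] = ppg_token(true);  // block begins with AV (or GB if artifact)
    }
    for (const Token& t : group) bb.write(t);

    if (!artifact) {
      prev = v;
      force_av = false;
    } else {
      force_av = true;  // resync with AV after garbage
    }
  }
  blocks.push_back(bb.finish());

  List out(blocks.size());
  for (size_t k = 0; k < blocks.size(); ++k) out[k] = blocks[k];
  return List::create(_["blocks"] = out, _["counters"] = wrap(counters));
}

namespace {

struct BitReader {
  const uint8_t* p;
  int nbits;
  int pos;
  BitReader(const uint8_t* p_, int nbits_) : p(p_), nbits(nbits_), pos(0) {}
  bool done() const { return pos >= nbits; }
  int bit() {
    int b = (p[pos >> 3] >> (7 - (pos & 7))) & 1;
    ++pos;
    return b;
  }
  uint32_t bits(int k) {
    uint32_t v = 0;
    for (int i = 0; i < k; ++i) v = (v << 1) | uint32_t(bit());
    return v;
  }
};

}  // namespace

// Decode one 4096-byte block. Returns the PPG values (NA where GB), the
// block's starting sample counter, auxiliary values with the 0-based index
// of the PPG sample they are bound to, and whether any GB token occurred.
// [[Rcpp::export]]
List cpp_decode_block(RawVector block) {
  if (block.size() < ROWS * ROW_BYTES) stop("block shorter than 3925 bytes");
  const uint8_t* raw = RAW(block);
  uint32_t counter = uint32_t(raw[0]) | (uint32_t(raw[1]) << 8) |
                     (uint32_t(raw[2]) << 16) | (uint32_t(raw[3]) << 24);

  std::vector<int> ppg;
  std::vector<int> spo2_i, spo2_v, move_i, move_v;
  bool has_gb = false, malformed = false;
  long prev = 0;
  long idx = long(counter);        // sample index of next PPG token
  long last_idx = long(counter) - 1;  // index of most recent PPG sample

  int off = 0;
  for (int r = 0; r < ROWS && !malformed; ++r) {
    int hdr = (r == 0) ? 4 : 0;
    int ub = int(raw[off + hdr]) | (int(raw[off + hdr + 1]) << 8);
    int cap = row_capacity(r);
    if (ub > cap) { malformed = true; break; }
    BitReader br(raw + off + hdr + 2, ub);
    off += ROW_BYTES;
    while (!br.done() && !malformed) {
      // prefix-free descriptor: count leading 1s (max 5)
      int ones = 0;
      while (ones < 5 && !br.done() && br.bit() == 1) ++ones;
      switch (ones) {
        case 0: {  // DD
          if (br.pos + 8 > br.nbits) { malformed = true; break; }
          int8_t d = int8_t(br.bits(8));
          prev += d;
          ppg.push_back(int(prev));
          last_idx = idx++;
          break;
        }
        case 1: {  // GB
          ppg.push_back(NA_INTEGER);
          has_gb = true;
          last_idx = idx++;
          break;
        }
        case 2: {  // AV
          if (br.pos + 18 > br.nbits) { malformed = true; break; }
          prev = long(br.bits(18));
          ppg.push_back(int(prev));
          last_idx = idx++;
          break;
        }
        case 3: {  // SF: 3-bit code + bare 8-bit signed quotient
          if (br.pos + 11 > br.nbits) { malformed = true; break; }
          int code = int(br.bits(3));
          int8_t q = int8_t(br.bits(8));
          prev += long(1L << (code + 1)) * q;
          ppg.push_back(int(prev));
          last_idx = idx++;
          break;
        }
        case 4: {  // SPO2
          if (br.pos + 6 > br.nbits) { malformed = true; break; }
          spo2_i.push_back(int(last_idx));
          spo2_v.push_back(int(br.bits(6)));
          break;
        }
        case 5: {  // MOVE
          if (br.done() || br.bit() != 0 || br.pos + 16 > br.nbits) {
            malformed = true;
            break;
          }
          move_i.push_back(int(last_idx));
          move_v.push_back(int(br.bits(16)));
          break;
        }
      }
    }
  }

  return List::create(
      _["counter"] = double(counter), _["ppg"] = wrap(ppg),
      _["spo2_idx"] = wrap(spo2_i), _["spo2_code"] = wrap(spo2_v),
      _["move_idx"] = wrap(move_i), _["move_val"] = wrap(move_v),
      _["has_gb"] = has_gb, _["malformed"] = malformed);
}

// Local maxima with topographic prominence >= min_prominence, thinned so no
// two retained peaks are closer than min_distance samples (taller peaks win).
// Returns 1-based indices in increasing order.
// [[Rcpp::export]]
IntegerVector cpp_find_peaks(NumericVector x, double min_prominence,
                             int min_distance) {
  int n = x.size();
  std::vector<int> cand;
  for (int i = 1; i + 1 < n; ++i) {
    if (x[i] <= x[i - 1]) continue;
    // plateau-aware: advance over equal samples; a peak needs a drop after
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    if (j + 1 < n && x[j + 1] < x[i]) cand.push_back((i + j) / 2);
    i = j;
  }
  std::vector<int> keep;
  std::vector<double> height;
  for (int p : cand) {
    double peak = x[p];
    double lmin = peak, rmin = peak;
    for (int j = p - 1; j >= 0; --j) {
      if (x[j] > peak) break;
      if (x[j] < lmin) lmin = x[j];
    }
    for (int j = p + 1; j < n; ++j) {
      if (x[j] > peak) break;
      if (x[j] < rmin) rmin = x[j];
    }
    double prom = peak - std::max(lmin, rmin);
    if (prom >= min_prominence) {
      keep.push_back(p);
      height.push_back(peak);
    }
  }
  // greedy tallest-first thinning; `keep` is sorted by index, so suppression
  // only needs a local walk around each accepted peak
  std::vector<size_t> ord(keep.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return height[a] > height[b]; });
  std::vector<bool> dead(keep.size(), false);
  std::vector<int> final_idx;
  for (size_t oi : ord) {
    if (dead[oi]) continue;
    final_idx.push_back(keep[oi]);
    for (size_t j = oi; j-- > 0 && keep[oi] - keep[j] < min_distance;)
      dead[j] = true;
    for (size_t j = oi + 1; j < keep.size() && keep[j] - keep[oi] < min_distance;
         ++j)
      dead[j] = true;
  }
  std::sort(final_idx.begin(), final_idx.end());
  IntegerVector out(final_idx.size());
  for (size_t i = 0; i < final_idx.size(); ++i) out[i] = final_idx[i] + 1;
  return out;
}
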