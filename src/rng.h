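#ifndef PHASIC_RNG_H
#define PHASIC_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ seeded through splitmix64. One independent stream per
// (master seed, stream id) pair, so ensembles are order-independent and
// reproducible regardless of how cells are scheduled.
class RngStream {
  uint64_t s[4];
  double spare;
  bool has_spare;

  static uint64_t sm64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

public:
  RngStream(uint64_t seed, uint64_t stream) : has_spare(false) {
    uint64_t x = seed ^ (0xD2B74407B1CE6E93ULL * (stream + 1ULL));
    for (int i = 0; i < 4; ++i) s[i] = sm64(x);
  }

  uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }

  // uniform on [0, 1) with 53-bit resolution
  double unif() { return (next() >> 11) * 1.1102230246251565e-16; }

  // standard normal via Box-Muller (cached pair)
  double normal() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1;
    do {
      u1 = unif();
    } while (u1 <= 0.0);
    const double u2 = unif();
    const double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(6.283185307179586 * u2);
    has_spare = true;
    return m * std::cos(6.283185307179586 * u2);
  }
};

#endif
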