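#ifndef MP_RNG_H
#define MP_RNG_H

#include <cstdint>
#include <cstdlib>
#include <cmath>

// Deterministic, platform-independent RNG for the Langevin integrator.
// mt19937_64 has a standard-specified stream; the normal sampler is our own
// ziggurat (Marsaglia-Tsang, 128 layers) because std::normal_distribution is
// implementation-defined.
struct MpRng {
    std::uint64_t mt[312];
    int mti;
    std::uint32_t kn[128];
    double wn[128], fn[128];

    explicit MpRng(std::uint64_t seed) : mti(313) {
        mt[0] = seed;
        for (int i = 1; i < 312; i++)
            mt[i] = 6364136223846793005ULL * (mt[i - 1] ^ (mt[i - 1] >> 62)) + (std::uint64_t)i;
        mti = 312;
        zigset();
    }

    std::uint64_t next_u64() {
        const std::uint64_t LM = 0x7FFFFFFFULL, UM = 0xFFFFFFFF80000000ULL;
        if (mti >= 312) {
            for (int i = 0; i < 312; i++) {
                std::uint64_t x = (mt[i] & UM) | (mt[(i + 1) % 312] & LM);
                mt[i] = mt[(i + 156) % 312] ^ (x >> 1);
                if (x & 1ULL) mt[i] ^= 0xB5026F5AA96619E9ULL;
            }
            mti = 0;
        }
        std::uint64_t x = mt[mti++];
        x ^= (x >> 29) & 0x5555555555555555ULL;
        x ^= (x << 17) & 0x71D67FFFEDA60000ULL;
        x ^= (x << 37) & 0xFFF7EEE000000000ULL;
        x ^= (x >> 43);
        return x;
    }

    // uniform in (0,1)
    double runif() {
        return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }

    void zigset() {
        double m1 = 2147483648.0;
        double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
        double q = vn / std::exp(-0.5 * dn * dn);
        kn[0] = (std::uint32_t)((dn / q) * m1);
        kn[1] = 0;
        wn[0] = q / m1;
        wn[127] = dn / m1;
        fn[0] = 1.0;
        fn[127] = std::exp(-0.5 * dn * dn);
        for (int i = 126; i >= 1; i--) {
            dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
            kn[i + 1] = (std::uint32_t)((dn / tn) * m1);
            tn = dn;
            fn[i] = std::exp(-0.5 * dn * dn);
            wn[i] = dn / m1;
        }
    }

    // standard normal
    double rnorm() {
        for (;;) {
            std::int32_t hz = (std::int32_t)(next_u64() >> 32);
            int iz = hz & 127;
            std::uint32_t ahz = (hz < 0) ? (std::uint32_t)(-(std::int64_t)hz)
                                         : (std::uint32_t)hz;
            if (ahz < kn[iz]) return hz * wn[iz];
            if (iz == 0) {                      // base strip: exact tail
                const double r = 3.442619855899;
                double x, y;
                do {
                    x = -std::log(runif()) / r;
                    y = -std::log(runif());
                } while (y + y < x * x);
                return (hz > 0) ? r + x : -(r + x);
            }
            double x = hz * wn[iz];
            if (fn[iz] + runif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
                return x;
        }
    }
};

#endif
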