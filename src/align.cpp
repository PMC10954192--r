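#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit encode A/C/G/T; -1 for anything else (N etc.)
static inline int base2bit(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
    return r;
}

struct AlnResult {
    bool ok = false;
    int score = 0;
    int ref_start = 0;       // 0-based on the (extended) reference
    std::string aln_read;    // gapped, ref-forward orientation
    std::string aln_ref;
    int edit = 0;
};

// Local alignment with affine gaps (gap of length g costs open + g*ext),
// full traceback of the best-scoring cell.  Read along rows, ref along cols.
static AlnResult smith_waterman(const std::string &read, const std::string &ref,
                                int match, int mismatch, int gap_open, int gap_ext) {
    const int m = (int) read.size(), n = (int) ref.size();
    AlnResult res;
    if (m == 0 || n == 0) return res;
    const int NEG = -1000000000;
    const int gi = gap_open + gap_ext;  // cost of opening (first gapped base)

    // reusable workspace (R is single-threaded); avoids per-call allocation
    static std::vector<int> H, E, F;
    static std::vector<unsigned char> tbH, tbE, tbF;
    const size_t need = (size_t)(m + 1) * (n + 1);
    if (H.size() < need) {
        H.resize(need); E.resize(need); F.resize(need);
        tbH.resize(need); tbE.resize(need); tbF.resize(need);
    }
    std::fill(H.begin(), H.begin() + need, 0);
    std::fill(E.begin(), E.begin() + need, NEG);  // gap in read (consumes ref)
    std::fill(F.begin(), F.begin() + need, NEG);  // gap in ref  (consumes read)
    // traceback: 0 stop, 1 diag, 2 from E, 3 from F
    std::fill(tbH.begin(), tbH.begin() + need, 0);
    std::fill(tbE.begin(), tbE.begin() + need, 0);  // 1 = open (from H), 0 = extend
    std::fill(tbF.begin(), tbF.begin() + need, 0);

    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            const int idx = i * (n + 1) + j;
            const int up = (i - 1) * (n + 1) + j;
            const int left = i * (n + 1) + (j - 1);
            const int diag = (i - 1) * (n + 1) + (j - 1);

            int e_open = H[left] - gi, e_ext = E[left] - gap_ext;
            if (e_open >= e_ext) { E[idx] = e_open; tbE[idx] = 1; }
            else                 { E[idx] = e_ext;  tbE[idx] = 0; }

            int f_open = H[up] - gi, f_ext = F[up] - gap_ext;
            if (f_open >= f_ext) { F[idx] = f_open; tbF[idx] = 1; }
            else                 { F[idx] = f_ext;  tbF[idx] = 0; }

            char a = read[i - 1], b = ref[j - 1];
            int s = (a == b && a != 'N') ? match : mismatch;
            int d = H[diag] + s;

            int h = 0; unsigned char t = 0;
            if (d > h) { h = d; t = 1; }
            if (E[idx] > h) { h = E[idx]; t = 2; }
            if (F[idx] > h) { h = F[idx]; t = 3; }
            H[idx] = h; tbH[idx] = t;
            // leftmost-then-topmost best cell for determinism
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    if (best <= 0) return res;

    std::string ar, af;
    int i = bi, j = bj;
    int state = 0;  // 0 = in H
    while (i > 0 && j > 0) {
        const int idx = i * (n + 1) + j;
        if (state == 0) {
            unsigned char t = tbH[idx];
            if (t == 0) break;
            if (t == 1) { ar.push_back(read[i - 1]); af.push_back(ref[j - 1]); --i; --j; }
            else if (t == 2) state = 2;
            else state = 3;
        } else if (state == 2) {  // gap in read
            ar.push_back('-'); af.push_back(ref[j - 1]);
            unsigned char t = tbE[idx];
            --j;
            if (t == 1) state = 0;
        } else {                  // gap in ref
            ar.push_back(read[i - 1]); af.push_back('-');
            unsigned char t = tbF[idx];
            --i;
            if (t == 1) state = 0;
        }
    }
    std::reverse(ar.begin(), ar.end());
    std::reverse(af.begin(), af.end());

    res.ok = true;
    res.score = best;
    res.ref_start = j;  // 0-based: alignment starts at ref position j (after tb, j = start-1 in 1-based)
    res.aln_read = ar;
    res.aln_ref = af;
    int ed = 0;
    for (size_t c = 0; c < ar.size(); ++c)
        if (ar[c] == '-' || af[c] == '-' || ar[c] != af[c]) ++ed;
    res.edit = ed;
    return res;
}

typedef std::unordered_map<uint32_t, std::vector<int> > KmerIndex;

static void build_index(const std::string &ref, int k, KmerIndex &idx) {
    const int n = (int) ref.size();
    if (n < k) return;
    uint32_t code = 0;
    const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
    int run = 0;  // number of consecutive valid bases ending here
    for (int i = 0; i < n; ++i) {
        int b = base2bit(ref[i]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t) b) & mask;
        ++run;
        if (run >= k) idx[code].push_back(i - k + 1);
    }
}

// Seed one read (one orientation) against the index, cluster seed diagonals,
// and run local DP on each clustered window.  Returns best alignment.
static AlnResult align_one(const std::string &read, const std::string &ref,
                           const KmerIndex &idx, int k,
                           int match, int mismatch, int gap_open, int gap_ext,
                           int margin) {
    AlnResult best;
    const int m = (int) read.size(), n = (int) ref.size();
    if (m < k) return best;

    std::vector<int> diags;
    uint32_t code = 0;
    const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
    int run = 0;
    for (int i = 0; i < m; ++i) {
        int b = base2bit(read[i]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t) b) & mask;
        ++run;
        if (run >= k) {
            KmerIndex::const_iterator it = idx.find(code);
            if (it != idx.end()) {
                int rpos = i - k + 1;
                for (size_t h = 0; h < it->second.size(); ++h)
                    diags.push_back(it->second[h] - rpos);
            }
        }
    }
    if (diags.empty()) return best;
    std::sort(diags.begin(), diags.end());

    // cluster diagonals closer than `margin`; evaluate each cluster window
    size_t s = 0;
    while (s < diags.size()) {
        size_t e = s;
        while (e + 1 < diags.size() && diags[e + 1] - diags[e] <= margin) ++e;
        int dmin = diags[s], dmax = diags[e];
        int w0 = std::max(0, dmin - margin);
        int w1 = std::min(n, dmax + m + margin);
        if (w1 > w0) {
            AlnResult r = smith_waterman(read, ref.substr(w0, w1 - w0),
                                         match, mismatch, gap_open, gap_ext);
            if (r.ok) {
                r.ref_start += w0;
                if (!best.ok || r.score > best.score ||
                    (r.score == best.score && r.ref_start < best.ref_start))
                    best = r;
            }
        }
        s = e + 1;
    }
    return best;
}

//' @noRd
// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref, int k,
                     int match, int mismatch, int gap_open, int gap_ext,
                     NumericVector min_score, int margin) {
    KmerIndex idx;
    build_index(ref, k, idx);
    const int nr = reads.size();
    NumericVector score(nr, NA_REAL);
    IntegerVector start0(nr, NA_INTEGER);
    IntegerVector edit(nr, NA_INTEGER);
    CharacterVector strand(nr, NA_STRING);
    CharacterVector aln_read(nr, NA_STRING);
    CharacterVector aln_ref(nr, NA_STRING);

    for (int i = 0; i < nr; ++i) {
        std::string rd = as<std::string>(reads[i]);
        AlnResult fw = align_one(rd, ref, idx, k, match, mismatch, gap_open, gap_ext, margin);
        AlnResult rv;
        // the reverse strand cannot beat a perfect forward hit
        if (!(fw.ok && fw.score >= (int) rd.size() * match)) {
            std::string rc = revcomp(rd);
            rv = align_one(rc, ref, idx, k, match, mismatch, gap_open, gap_ext, margin);
        }
        AlnResult *b = NULL;
        bool minus = false;
        if (fw.ok && (!rv.ok || fw.score >= rv.score)) b = &fw;
        else if (rv.ok) { b = &rv; minus = true; }
        if (b && b->score >= min_score[i]) {
            score[i] = b->score;
            start0[i] = b->ref_start;
            edit[i] = b->edit;
            strand[i] = minus ? "-" : "+";
            aln_read[i] = b->aln_read;
            aln_ref[i] = b->aln_ref;
        }
    }
    return List::create(_["score"] = score, _["ref_start"] = start0,
                        _["edit_distance"] = edit, _["strand"] = strand,
                        _["aln_read"] = aln_read, _["aln_ref"] = aln_ref);
}

//' @noRd
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2rc, CharacterVector qual2rev,
                     int min_overlap, double max_mismatch_rate) {
    const int n = seq1.size();
    CharacterVector mseq(n, NA_STRING), mqual(n, NA_STRING);
    IntegerVector overlap(n, NA_INTEGER);

    for (int i = 0; i < n; ++i) {
        std::string s1 = as<std::string>(seq1[i]);
        std::string q1 = as<std::string>(qual1[i]);
        std::string s2 = as<std::string>(seq2rc[i]);
        std::string q2 = as<std::string>(qual2rev[i]);
        const int L1 = (int) s1.size(), L2 = (int) s2.size();
        if (L1 == 0 || L2 == 0) stop("empty sequence in read pair %d", i + 1);
        const int maxov = std::min(L1, L2);

        int best_score = -1, best_ov = -1;
        for (int ov = min_overlap; ov <= maxov; ++ov) {
            int mm = 0;
            const int off1 = L1 - ov;
            for (int p = 0; p < ov; ++p) {
                char a = s1[off1 + p], b = s2[p];
                if (a != b || a == 'N') ++mm;  // N counts as mismatch
            }
            if ((double) mm / ov > max_mismatch_rate) continue;
            int sc = ov - 2 * mm;  // matches - mismatches
            if (sc > best_score || (sc == best_score && ov > best_ov)) {
                best_score = sc; best_ov = ov;
            }
        }
        if (best_ov < 0) continue;  // unmerged

        const int off1 = L1 - best_ov;
        std::string os = s1.substr(0, off1);
        std::string oq = q1.substr(0, off1);
        for (int p = 0; p < best_ov; ++p) {
            char a = s1[off1 + p], b = s2[p];
            char aq = q1[off1 + p], bq = q2[p];
            if (aq >= bq) os.push_back(a); else os.push_back(b);
            oq.push_back(std::max(aq, bq));
        }
        os += s2.substr(best_ov);
        oq += q2.substr(best_ov);
        mseq[i] = os; mqual[i] = oq; overlap[i] = best_ov;
    }
    return List::create(_["seq"] = mseq, _["qual"] = mqual, _["overlap"] = overlap);
}
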