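// Greedy BPE training and application on integer token id sequences.
// Each iteration recounts all adjacent pairs from scratch over the corpus
// (non-overlapping left-to-right within a sequence, so "AAA" holds one "AA"),
// merges every occurrence of the most frequent pair, and records the merge.
// Ties are broken lexicographically on the concatenated token string.
#include <Rcpp.h>
#include <map>
using namespace Rcpp;

typedef std::pair<int, int> IPair;

// non-overlapping pair counts for one sequence (0-based ids)
static void count_pairs(const std::vector<int>& t, std::map<IPair, long>& cnt) {
  const int n = (int)t.size();
  int i = 0;
  while (i < n - 1) {
    if (t[i] == t[i + 1]) {
      int j = i;
      while (j < n && t[j] == t[i]) ++j; // run [i, j)
      cnt[IPair(t[i], t[i])] += (j - i) / 2;
      if (j < n) cnt[IPair(t[j - 1], t[j])] += 1; // heterogeneous pair at run end
      i = j;
    } else {
      cnt[IPair(t[i], t[i + 1])] += 1;
      ++i;
    }
  }
}

// greedy left-to-right replacement of (a,b) -> nid
static void replace_pair(std::vector<int>& t, int a, int b, int nid) {
  const int n = (int)t.size();
  std::vector<int> out;
  out.reserve(n);
  int i = 0;
  while (i < n) {
    if (i < n - 1 && t[i] == a && t[i + 1] == b) {
      out.push_back(nid);
      i += 2;
    } else {
      out.push_back(t[i]);
      ++i;
    }
  }
  t.swap(out);
}

// [[Rcpp::export]]
List cpp_bpe_train(List seqs, CharacterVector tok_strings, int max_new_merges,
                   int min_count, int n_frozen) {
  std::vector<std::vector<int>> corpus(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    IntegerVector v = seqs[s];
    corpus[s].assign(v.begin(), v.end());
    for (int& x : corpus[s]) x -= 1; // to 0-based
  }
  std::vector<std::string> toks(tok_strings.size());
  for (int i = 0; i < tok_strings.size(); ++i) toks[i] = as<std::string>(tok_strings[i]);

  std::vector<IPair> merges;
  std::vector<std::string> new_tokens;

  for (int it = 0; it < max_new_merges; ++it) {
    std::map<IPair, long> cnt;
    for (auto& t : corpus) count_pairs(t, cnt);
    long best = 0;
    IPair bp(-1, -1);
    std::string bstr;
    for (auto& kv : cnt) {
      if (kv.second < min_count) continue;
      // special tokens and the ambiguity symbol never participate in merges
      if (kv.first.first < n_frozen || kv.first.second < n_frozen) continue;
      std::string s = toks[kv.first.first] + toks[kv.first.second];
      if (kv.second > best || (kv.second == best && s < bstr)) {
        best = kv.second;
        bp = kv.first;
        bstr = s;
      }
    }
    if (best < min_count || bp.first < 0) break;
    int nid = (int)toks.size();
    toks.push_back(bstr);
    new_tokens.push_back(bstr);
    merges.push_back(bp);
    for (auto& t : corpus) replace_pair(t, bp.first, bp.second, nid);
  }

  IntegerMatrix M(merges.size(), 2);
  for (size_t k = 0; k < merges.size(); ++k) {
    M(k, 0) = merges[k].first + 1;
    M(k, 1) = merges[k].second + 1;
  }
  return List::create(_["merges"] = M,
                      _["new_tokens"] = wrap(new_tokens));
}

// Apply recorded merges in order to a single sequence of 1-based ids.
// merged_ids gives the id assigned to each merge's concatenation.
// [[Rcpp::export]]
IntegerVector cpp_apply_merges(IntegerVector seq, IntegerMatrix merges,
                               IntegerVector merged_ids) {
  std::vector<int> t(seq.begin(), seq.end());
  for (int k = 0; k < merges.nrow(); ++k) {
    if ((int)t.size() < 2) break;
    replace_pair(t, merges(k, 0), merges(k, 1), merged_ids[k]);
  }
  return wrap(t);
}
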