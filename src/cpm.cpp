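// Core lattice engine: cellular Potts Metropolis dynamics with a
// membrane-bound particle layer, plus small voxel utilities (3D median
// filter, connected-component labelling) that need tight loops.
//
// Conventions: lattice id 0 = medium, >= 1 = cells. All coordinates are
// 0-based inside this file; R-facing wrappers convert. Adjacency for
// interfaces/surfaces/boundaries is 6-face; copy attempts use the
// 26-neighbourhood. Sites in the 1-voxel frame of the lattice are frozen
// medium (copy targets there are rejected), so cells cannot touch the edge.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int OFF6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

struct Offsets {
  // 26-neighbourhood
  std::vector<std::array<int,3>> o26;
  // offsets grouped by squared distance (ascending), within radius 6,
  // used for nearest-boundary reattachment
  std::vector<std::pair<int, std::vector<std::array<int,3>>>> shells;
  Offsets() {
    for (int dz=-1; dz<=1; ++dz) for (int dy=-1; dy<=1; ++dy)
      for (int dx=-1; dx<=1; ++dx)
        if (dx||dy||dz) o26.push_back({dx,dy,dz});
    const int R = 6;
    std::vector<std::pair<int,std::array<int,3>>> all;
    for (int dz=-R; dz<=R; ++dz) for (int dy=-R; dy<=R; ++dy)
      for (int dx=-R; dx<=R; ++dx) {
        int d2 = dx*dx+dy*dy+dz*dz;
        if (d2>0 && d2<=R*R) all.push_back({d2,{dx,dy,dz}});
      }
    std::sort(all.begin(), all.end(),
              [](const std::pair<int,std::array<int,3>> &a,
                 const std::pair<int,std::array<int,3>> &b){return a.first<b.first;});
    for (auto &p : all) {
      if (shells.empty() || shells.back().first != p.first)
        shells.push_back({p.first, {}});
      shells.back().second.push_back(p.second);
    }
  }
};
static Offsets OFFS;

static inline int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

struct CPMState {
  int nx, ny, nz, n;
  std::vector<int> ids;
  // params
  double j_cm, j_cc, lambda_v, lambda_s, temp;
  std::vector<double> target_v, target_s;  // indexed by id-1
  int max_id;
  // caches
  std::vector<double> vol, surf;
  double H;
  // particles
  std::vector<int> px, py, pz, pcolor, pcell;
  std::vector<int> head, nxt, prv;  // per-site particle lists
  // per-colour diffusion step (lattice lengths per mcs)
  std::vector<double> step_by_color;

  inline int idx(int x, int y, int z) const { return x + nx*(y + ny*z); }
  inline bool inb(int x, int y, int z) const {
    return x>=0 && x<nx && y>=0 && y<ny && z>=0 && z<nz;
  }
  inline int at(int x, int y, int z) const {
    return inb(x,y,z) ? ids[idx(x,y,z)] : 0;  // out of bounds = medium
  }
  inline bool in_frame(int x, int y, int z) const {
    return x==0 || y==0 || z==0 || x==nx-1 || y==ny-1 || z==nz-1;
  }
  inline double Jpair(int a, int b) const {
    if (a == b) return 0.0;
    return (a == 0 || b == 0) ? j_cm : j_cc;
  }
  inline double tv(int c) const {
    return (c >= 1 && c <= (int)target_v.size()) ? target_v[c-1] : 0.0;
  }
  inline double ts(int c) const {
    return (c >= 1 && c <= (int)target_s.size()) ? target_s[c-1] : 0.0;
  }

  void init_lattice(const IntegerVector &arr, const List &params) {
    IntegerVector d = arr.attr("dim");
    nx = d[0]; ny = d[1]; nz = d[2]; n = nx*ny*nz;
    ids.assign(arr.begin(), arr.end());
    j_cm = as<double>(params["j_cell_medium"]);
    j_cc = as<double>(params["j_cell_cell"]);
    lambda_v = as<double>(params["lambda_v"]);
    lambda_s = as<double>(params["lambda_s"]);
    temp = as<double>(params["temperature"]);
    NumericVector Tv = params["target_volume"], Ts = params["target_surface"];
    target_v.assign(Tv.begin(), Tv.end());
    target_s.assign(Ts.begin(), Ts.end());
    max_id = 0;
    for (int v : ids) if (v > max_id) max_id = v;
    if ((int)target_v.size() < max_id || (int)target_s.size() < max_id)
      stop("target_volume/target_surface must have one entry per cell id");
    recompute_caches();
  }

  void recompute_caches() {
    vol.assign(max_id+1, 0.0);
    surf.assign(max_id+1, 0.0);
    double e_int = 0.0;
    for (int z=0; z<nz; ++z) for (int y=0; y<ny; ++y) for (int x=0; x<nx; ++x) {
      int c = ids[idx(x,y,z)];
      if (c > 0) vol[c] += 1.0;
      for (int k=0; k<6; ++k) {
        int nb = at(x+OFF6[k][0], y+OFF6[k][1], z+OFF6[k][2]);
        if (c > 0 && nb != c) surf[c] += 1.0;
        // count each unordered in-bounds pair once (k even = +direction)
        if (k % 2 == 0 && inb(x+OFF6[k][0], y+OFF6[k][1], z+OFF6[k][2]))
          e_int += Jpair(c, nb);
      }
    }
    H = e_int;
    for (int c=1; c<=max_id; ++c) {
      if (vol[c] > 0 || tv(c) > 0) {
        double dv = vol[c]-tv(c), ds = surf[c]-ts(c);
        H += lambda_v*dv*dv + lambda_s*ds*ds;
      }
    }
  }

  inline bool is_boundary(int x, int y, int z, int cell) const {
    if (at(x,y,z) != cell) return false;
    for (int k=0; k<6; ++k)
      if (at(x+OFF6[k][0], y+OFF6[k][1], z+OFF6[k][2]) != cell) return true;
    return false;
  }

  // Delta-H for copying the id at source into target (ids differ).
  double delta_h(int sx, int sy, int sz, int tx, int ty, int tz) const {
    int ss = at(sx,sy,sz), st = at(tx,ty,tz);
    double dE = 0.0;
    int same_t = 0, same_s = 0;
    for (int k=0; k<6; ++k) {
      int nb = at(tx+OFF6[k][0], ty+OFF6[k][1], tz+OFF6[k][2]);
      dE += Jpair(ss, nb) - Jpair(st, nb);
      if (nb == st) ++same_t;
      if (nb == ss) ++same_s;
    }
    if (st > 0) {
      double v = vol[st], s = surf[st];
      double ds = 2.0*same_t - 6.0;
      dE += lambda_v*((v-1-tv(st))*(v-1-tv(st)) - (v-tv(st))*(v-tv(st)));
      dE += lambda_s*((s+ds-ts(st))*(s+ds-ts(st)) - (s-ts(st))*(s-ts(st)));
    }
    if (ss > 0) {
      double v = vol[ss], s = surf[ss];
      double ds = 6.0 - 2.0*same_s;
      dE += lambda_v*((v+1-tv(ss))*(v+1-tv(ss)) - (v-tv(ss))*(v-tv(ss)));
      dE += lambda_s*((s+ds-ts(ss))*(s+ds-ts(ss)) - (s-ts(ss))*(s-ts(ss)));
    }
    return dE;
  }

  void apply_copy(int sx, int sy, int sz, int tx, int ty, int tz, double dH) {
    int ss = at(sx,sy,sz), st = at(tx,ty,tz);
    int same_t = 0, same_s = 0;
    for (int k=0; k<6; ++k) {
      int nb = at(tx+OFF6[k][0], ty+OFF6[k][1], tz+OFF6[k][2]);
      if (nb == st) ++same_t;
      if (nb == ss) ++same_s;
    }
    if (st > 0) { vol[st] -= 1.0; surf[st] += 2.0*same_t - 6.0; }
    if (ss > 0) { vol[ss] += 1.0; surf[ss] += 6.0 - 2.0*same_s; }
    ids[idx(tx,ty,tz)] = ss;
    H += dH;
  }

  // ---- particle layer ----
  void init_particles(const IntegerMatrix &p, const NumericVector &steps) {
    int m = p.nrow();
    px.resize(m); py.resize(m); pz.resize(m);
    pcolor.resize(m); pcell.resize(m);
    head.assign(n, -1); nxt.assign(m, -1); prv.assign(m, -1);
    for (int i=0; i<m; ++i) {
      px[i]=p(i,0); py[i]=p(i,1); pz[i]=p(i,2); pcolor[i]=p(i,3);
      int s = idx(px[i],py[i],pz[i]);
      pcell[i] = ids[s];
      if (pcell[i] <= 0) stop("particle not on a cell site");
      link_particle(i, s);
    }
    step_by_color.assign(steps.begin(), steps.end());
  }
  inline void link_particle(int i, int s) {
    nxt[i] = head[s]; prv[i] = -1;
    if (head[s] >= 0) prv[head[s]] = i;
    head[s] = i;
  }
  inline void unlink_particle(int i, int s) {
    if (prv[i] >= 0) nxt[prv[i]] = nxt[i]; else head[s] = nxt[i];
    if (nxt[i] >= 0) prv[nxt[i]] = prv[i];
  }
  inline void move_particle(int i, int xs, int ysv, int zs) {
    unlink_particle(i, idx(px[i],py[i],pz[i]));
    px[i]=xs; py[i]=ysv; pz[i]=zs;
    link_particle(i, idx(xs,ysv,zs));
  }

  // move a stranded particle to one of the nearest boundary sites of its cell
  void reattach_particle(int i) {
    int cell = pcell[i];
    int x0 = px[i], y0 = py[i], z0 = pz[i];
    for (auto &shell : OFFS.shells) {
      std::vector<std::array<int,3>> cand;
      for (auto &o : shell.second) {
        int x = x0+o[0], y = y0+o[1], z = z0+o[2];
        if (is_boundary(x,y,z,cell)) cand.push_back({x,y,z});
      }
      if (!cand.empty()) {
        auto &c = cand[runif_int((int)cand.size())];
        move_particle(i, c[0], c[1], c[2]);
        return;
      }
    }
    // fallback: exhaustive nearest-boundary scan
    long best_d2 = -1;
    std::vector<std::array<int,3>> cand;
    for (int z=0; z<nz; ++z) for (int y=0; y<ny; ++y) for (int x=0; x<nx; ++x) {
      if (!is_boundary(x,y,z,cell)) continue;
      long dx=x-x0, dy=y-y0, dz=z-z0;
      long d2 = dx*dx+dy*dy+dz*dz;
      if (best_d2 < 0 || d2 < best_d2) { best_d2 = d2; cand.clear(); }
      if (d2 == best_d2) cand.push_back({x,y,z});
    }
    if (cand.empty())
      stop("cell %d has no boundary sites left (cell annihilated)", cell);
    auto &c = cand[runif_int((int)cand.size())];
    move_particle(i, c[0], c[1], c[2]);
  }

  // after an accepted copy into (tx,ty,tz), particles on that site or its
  // 6-neighbours may have lost boundary status
  void fix_particles_near(int tx, int ty, int tz) {
    if (px.empty()) return;
    std::array<int,7> sites;
    int m = 0;
    sites[m++] = idx(tx,ty,tz);
    for (int k=0; k<6; ++k) {
      int x = tx+OFF6[k][0], y = ty+OFF6[k][1], z = tz+OFF6[k][2];
      if (inb(x,y,z)) sites[m++] = idx(x,y,z);
    }
    for (int j=0; j<m; ++j) {
      int s = sites[j];
      int i = head[s];
      while (i >= 0) {
        int nexti = nxt[i];
        int x = px[i], y = py[i], z = pz[i];
        if (!is_boundary(x, y, z, pcell[i])) reattach_particle(i);
        i = nexti;
      }
    }
  }

  // one annulus diffusion sweep (called at the end of each mcs)
  void diffuse_once() {
    std::vector<std::array<int,3>> cand;
    for (size_t i=0; i<px.size(); ++i) {
      double s = step_by_color[pcolor[i]];
      if (s <= 0) continue;
      double lo = s - 0.5, hi = s + 0.5;
      cand.clear();
      int R = (int)std::ceil(hi);
      for (int dz=-R; dz<=R; ++dz) for (int dy=-R; dy<=R; ++dy)
        for (int dx=-R; dx<=R; ++dx) {
          double d = std::sqrt((double)(dx*dx+dy*dy+dz*dz));
          if (d <= lo || d >= hi) continue;
          int x = px[i]+dx, y = py[i]+dy, z = pz[i]+dz;
          if (is_boundary(x, y, z, pcell[i])) cand.push_back({x,y,z});
        }
      if (!cand.empty()) {
        auto &c = cand[runif_int((int)cand.size())];
        move_particle(i, c[0], c[1], c[2]);
      }
    }
  }

  // returns true on acceptance
  bool attempt() {
    int i = runif_int(n);
    int z = i / (nx*ny), r = i % (nx*ny), y = r / nx, x = r % nx;
    const auto &o = OFFS.o26[runif_int(26)];
    int tx = x+o[0], ty = y+o[1], tz = z+o[2];
    if (!inb(tx,ty,tz) || in_frame(tx,ty,tz)) return false;
    if (ids[idx(tx,ty,tz)] == ids[idx(x,y,z)]) return false;
    double dH = delta_h(x,y,z, tx,ty,tz);
    if (dH < 0 || unif_rand() < std::exp(-dH/temp)) {
      apply_copy(x,y,z, tx,ty,tz, dH);
      fix_particles_near(tx,ty,tz);
      return true;
    }
    return false;
  }

  IntegerVector ids_out() const {
    IntegerVector out(ids.begin(), ids.end());
    out.attr("dim") = IntegerVector::create(nx, ny, nz);
    return out;
  }
  IntegerMatrix particles_out() const {
    int m = (int)px.size();
    IntegerMatrix out(m, 5);
    for (int i=0; i<m; ++i) {
      out(i,0)=px[i]; out(i,1)=py[i]; out(i,2)=pz[i];
      out(i,3)=pcolor[i]; out(i,4)=pcell[i];
    }
    return out;
  }
};

// [[Rcpp::export]]
List cpp_cpm_run(IntegerVector ids, List params, IntegerMatrix particles,
                 NumericVector step_by_color, int n_mcs, double s_division,
                 bool record_log) {
  CPMState st;
  st.init_lattice(ids, params);
  st.init_particles(particles, step_by_color);
  int watch = 1;  // the mother cell
  NumericMatrix log(record_log ? n_mcs : 0, 3);
  long attempts = 0, accepted = 0;
  int mcs_done = 0;
  bool triggered = false;
  // the trigger fires on the first downward crossing: it arms once the
  // surface has been above s_division at the end of some mcs
  bool armed = s_division > 0 && st.surf[watch] > s_division;
  for (int m=0; m<n_mcs; ++m) {
    for (int a=0; a<st.n; ++a) { ++attempts; if (st.attempt()) ++accepted; }
    st.diffuse_once();
    ++mcs_done;
    if (record_log) {
      log(m,0) = st.vol[watch]; log(m,1) = st.surf[watch]; log(m,2) = st.H;
    }
    if (s_division > 0 && st.vol[watch] > 0) {
      if (!armed) {
        if (st.surf[watch] > s_division) armed = true;
      } else if (st.surf[watch] <= s_division) {
        triggered = true;
        break;
      }
    }
    if (m % 16 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix logout = record_log ?
    NumericMatrix(log(Range(0, std::max(mcs_done-1,0)), Range(0,2))) : log;
  return List::create(
    _["ids"] = st.ids_out(), _["particles"] = st.particles_out(),
    _["mcs"] = mcs_done, _["triggered"] = triggered,
    _["attempts"] = (double)attempts, _["accepted"] = (double)accepted,
    _["hamiltonian"] = st.H, _["volume"] = st.vol[watch],
    _["surface"] = st.surf[watch], _["log"] = logout);
}

// Run bare copy attempts (no particles, no diffusion); for energy audits.
// [[Rcpp::export]]
List cpp_cpm_attempts(IntegerVector ids, List params, int n_attempts) {
  CPMState st;
  st.init_lattice(ids, params);
  st.init_particles(IntegerMatrix(0,4), NumericVector::create(1.0, 2.0));
  long accepted = 0;
  for (int a=0; a<n_attempts; ++a) if (st.attempt()) ++accepted;
  return List::create(_["ids"] = st.ids_out(),
                      _["hamiltonian_cached"] = st.H,
                      _["accepted"] = (double)accepted);
}

// [[Rcpp::export]]
List cpp_hamiltonian(IntegerVector ids, List params) {
  CPMState st;
  st.init_lattice(ids, params);
  NumericVector v(st.max_id), s(st.max_id);
  for (int c=1; c<=st.max_id; ++c) { v[c-1]=st.vol[c]; s[c-1]=st.surf[c]; }
  return List::create(_["H"] = st.H, _["volume"] = v, _["surface"] = s);
}

// source/target as 0-based (x,y,z) triples
// [[Rcpp::export]]
double cpp_delta_h(IntegerVector ids, List params,
                   IntegerVector source, IntegerVector target) {
  CPMState st;
  st.init_lattice(ids, params);
  int ss = st.at(source[0],source[1],source[2]);
  int tt = st.at(target[0],target[1],target[2]);
  if (ss == tt) stop("source and target carry the same cell id (no-op)");
  return st.delta_h(source[0],source[1],source[2],
                    target[0],target[1],target[2]);
}

// [[Rcpp::export]]
IntegerMatrix cpp_boundary_sites(IntegerVector ids, int cell) {
  CPMState st;
  List params = List::create(
    _["j_cell_medium"]=0.0, _["j_cell_cell"]=0.0, _["lambda_v"]=0.0,
    _["lambda_s"]=0.0, _["temperature"]=1.0,
    _["target_volume"]=NumericVector(std::max(cell,1)),
    _["target_surface"]=NumericVector(std::max(cell,1)));
  st.init_lattice(ids, params);
  std::vector<std::array<int,3>> out;
  for (int z=0; z<st.nz; ++z) for (int y=0; y<st.ny; ++y)
    for (int x=0; x<st.nx; ++x)
      if (st.is_boundary(x,y,z,cell)) out.push_back({x,y,z});
  IntegerMatrix m((int)out.size(), 3);
  for (size_t i=0; i<out.size(); ++i) {
    m(i,0)=out[i][0]; m(i,1)=out[i][1]; m(i,2)=out[i][2];
  }
  return m;
}

// one standalone diffusion sweep over the particle set
// [[Rcpp::export]]
IntegerMatrix cpp_diffuse_particles(IntegerVector ids, List params,
                                    IntegerMatrix particles,
                                    NumericVector step_by_color) {
  CPMState st;
  st.init_lattice(ids, params);
  st.init_particles(particles, step_by_color);
  st.diffuse_once();
  return st.particles_out();
}

// reattach every particle not currently on a boundary site of its cell
// [[Rcpp::export]]
IntegerMatrix cpp_reattach_particles(IntegerVector ids, List params,
                                     IntegerMatrix particles) {
  CPMState st;
  st.init_lattice(ids, params);
  st.init_particles(particles, NumericVector::create(1.0, 2.0));
  for (size_t i=0; i<st.px.size(); ++i)
    if (!st.is_boundary(st.px[i], st.py[i], st.pz[i], st.pcell[i]))
      st.reattach_particle((int)i);
  return st.particles_out();
}

// ---- voxel utilities ----

// 3D median filter with nearest-border replication
// [[Rcpp::export]]
NumericVector cpp_median_filter3d(NumericVector arr, int radius) {
  IntegerVector d = arr.attr("dim");
  int nx=d[0], ny=d[1], nz=d[2];
  NumericVector out(arr.size());
  out.attr("dim") = d;
  int w = 2*radius+1, k = w*w*w;
  std::vector<double> buf(k);
  for (int z=0; z<nz; ++z) for (int y=0; y<ny; ++y) for (int x=0; x<nx; ++x) {
    int m = 0;
    for (int dz=-radius; dz<=radius; ++dz)
      for (int dy=-radius; dy<=radius; ++dy)
        for (int dx=-radius; dx<=radius; ++dx) {
          int xx = std::min(std::max(x+dx,0), nx-1);
          int yy = std::min(std::max(y+dy,0), ny-1);
          int zz = std::min(std::max(z+dz,0), nz-1);
          buf[m++] = arr[xx + nx*(yy + (R_xlen_t)ny*zz)];
        }
    std::nth_element(buf.begin(), buf.begin()+k/2, buf.end());
    out[x + nx*(y + (R_xlen_t)ny*z)] = buf[k/2];
  }
  return out;
}

// label foreground components (BFS); labels assigned in scan order, so the
// component containing the lexicographically smallest seed gets label 1
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int nx=d[0], ny=d[1], nz=d[2];
  std::vector<std::array<int,3>> offs;
  for (int dz=-1; dz<=1; ++dz) for (int dy=-1; dy<=1; ++dy)
    for (int dx=-1; dx<=1; ++dx) {
      int m = std::abs(dx)+std::abs(dy)+std::abs(dz);
      if (m == 0) continue;
      if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
        continue;
      offs.push_back({dx,dy,dz});
    }
  IntegerVector lab(mask.size());
  lab.attr("dim") = d;
  int next = 0;
  std::vector<int> stack;
  for (int z=0; z<nz; ++z) for (int y=0; y<ny; ++y) for (int x=0; x<nx; ++x) {
    int i = x + nx*(y + ny*z);
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    stack.clear(); stack.push_back(i);
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back();
      int zz = j/(nx*ny), rr = j%(nx*ny), yy = rr/nx, xx = rr%nx;
      for (auto &o : offs) {
        int ax=xx+o[0], ay=yy+o[1], az=zz+o[2];
        if (ax<0||ax>=nx||ay<0||ay>=ny||az<0||az>=nz) continue;
        int jj = ax + nx*(ay + ny*az);
        if (mask[jj] && !lab[jj]) { lab[jj] = next; stack.push_back(jj); }
      }
    }
  }
  return lab;
}
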