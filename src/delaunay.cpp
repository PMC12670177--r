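// Incremental Bowyer-Watson Delaunay triangulation in 2D and 3D, plus the
// alpha-complex extraction used by the canopy reconstruction.
//
// Coordinates are rescaled to the unit box before triangulation (Delaunay is
// similarity-invariant); circumradii reported to R are computed from the
// original coordinates so that alpha keeps units of meters.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double ORIENT_EPS = 1e-13;

static inline uint64_t edgeKey2(int a, int b) {
  return a < b ? (((uint64_t)a << 32) | (uint64_t)b) : (((uint64_t)b << 32) | (uint64_t)a);
}

// ---------------------------------------------------------------- 3D engine

struct Tet {
  int v[4];    // vertex ids, orient(v0,v1,v2,v3) > 0
  int nb[4];   // neighbor opposite v[i], -1 if none
  bool alive;
  double cc[3]; // circumcenter (scaled coords)
  double r2;    // squared circumradius (scaled coords)
};

class Delaunay3D {
public:
  std::vector<double> px, py, pz; // scaled coords incl. 4 super vertices
  std::vector<Tet> tets;
  int n;          // number of real points
  int lastTet;

  double orient(int a, int b, int c, int d) const {
    double adx = px[a]-px[d], ady = py[a]-py[d], adz = pz[a]-pz[d];
    double bdx = px[b]-px[d], bdy = py[b]-py[d], bdz = pz[b]-pz[d];
    double cdx = px[c]-px[d], cdy = py[c]-py[d], cdz = pz[c]-pz[d];
    return adx*(bdy*cdz-bdz*cdy) - ady*(bdx*cdz-bdz*cdx) + adz*(bdx*cdy-bdy*cdx);
  }

  bool circum(Tet &t) {
    // Solve for circumcenter; returns false on near-degenerate tet.
    int a=t.v[0], b=t.v[1], c=t.v[2], d=t.v[3];
    double bax=px[b]-px[a], bay=py[b]-py[a], baz=pz[b]-pz[a];
    double cax=px[c]-px[a], cay=py[c]-py[a], caz=pz[c]-pz[a];
    double dax=px[d]-px[a], day=py[d]-py[a], daz=pz[d]-pz[a];
    double b2=bax*bax+bay*bay+baz*baz;
    double c2=cax*cax+cay*cay+caz*caz;
    double d2=dax*dax+day*day+daz*daz;
    double det = bax*(cay*daz-caz*day) - bay*(cax*daz-caz*dax) + baz*(cax*day-cay*dax);
    if (std::fabs(det) < 1e-300) return false;
    double ox = (b2*(cay*daz-caz*day) - bay*(c2*daz-d2*caz) + baz*(c2*day-d2*cay)) / (2*det);
    double oy = (bax*(c2*daz-d2*caz) - b2*(cax*daz-caz*dax) + baz*(cax*d2-c2*dax)) / (2*det);
    double oz = (bax*(cay*d2-c2*day) - bay*(cax*d2-c2*dax) + b2*(cax*day-cay*dax)) / (2*det);
    t.cc[0]=px[a]+ox; t.cc[1]=py[a]+oy; t.cc[2]=pz[a]+oz;
    t.r2 = ox*ox+oy*oy+oz*oz;
    return true;
  }

  bool inSphere(const Tet &t, int p) const {
    double dx=px[p]-t.cc[0], dy=py[p]-t.cc[1], dz=pz[p]-t.cc[2];
    return dx*dx+dy*dy+dz*dz < t.r2 * (1.0 + 1e-12);
  }

  void init(int npts) {
    n = npts;
    // super tetrahedron enclosing the unit box: {x,y,z >= -R, x+y+z <= R}
    double R = 1e4;
    double sx[4] = {-R,  3 * R, -R,    -R};
    double sy[4] = {-R, -R,     3 * R, -R};
    double sz[4] = {-R, -R,    -R,      3 * R};
    // perturb to avoid exact degeneracies with data
    for (int i = 0; i < 4; i++) {
      px.push_back(sx[i] + 0.001*(i+1));
      py.push_back(sy[i] + 0.002*(i+2));
      pz.push_back(sz[i] - 0.0013*(i+1));
    }
    Tet t; t.alive = true;
    t.v[0]=n; t.v[1]=n+1; t.v[2]=n+2; t.v[3]=n+3;
    if (orient(t.v[0],t.v[1],t.v[2],t.v[3]) < 0) std::swap(t.v[2], t.v[3]);
    t.nb[0]=t.nb[1]=t.nb[2]=t.nb[3]=-1;
    circum(t);
    tets.push_back(t);
    lastTet = 0;
  }

  int locate(int p) {
    int cur = lastTet;
    if (cur < 0 || !(size_t)(cur < (int)tets.size()) || !tets[cur].alive) cur = -1;
    if (cur < 0) {
      for (int i = (int)tets.size()-1; i >= 0; i--) if (tets[i].alive) { cur = i; break; }
    }
    int steps = 0, maxSteps = (int)tets.size() * 4 + 64;
    while (steps++ < maxSteps) {
      const Tet &t = tets[cur];
      int next = -1;
      for (int i = 0; i < 4; i++) {
        // face opposite v[i]; p on opposite side of that face from v[i]?
        int a = t.v[(i+1)&3], b = t.v[(i+2)&3], c = t.v[(i+3)&3];
        double op = orient(a, b, c, t.v[i]);
        double oq = orient(a, b, c, p);
        if (op * oq < -ORIENT_EPS) { // strictly opposite sides
          if (t.nb[i] >= 0) { next = t.nb[i]; break; }
        }
      }
      if (next < 0) return cur;
      cur = next;
    }
    // walk failed (numerical cycling): brute-force scan over circumspheres
    for (int i = 0; i < (int)tets.size(); i++)
      if (tets[i].alive && inSphere(tets[i], p)) return i;
    return cur;
  }

  // Insert point p. Returns false when numerically stuck (caller jitters).
  bool insert(int p) {
    int t0 = locate(p);
    if (!inSphere(tets[t0], p)) {
      // point may sit exactly on a face; search neighbors, then everywhere
      bool found = false;
      for (int i = 0; i < 4 && !found; i++) {
        int nb = tets[t0].nb[i];
        if (nb >= 0 && tets[nb].alive && inSphere(tets[nb], p)) { t0 = nb; found = true; }
      }
      if (!found) {
        for (int i = (int)tets.size() - 1; i >= 0; i--)
          if (tets[i].alive && inSphere(tets[i], p)) { t0 = i; found = true; break; }
      }
      if (!found) return false;
    }
    // BFS for the cavity (bad tets)
    std::vector<int> bad;
    std::vector<int> stack; stack.push_back(t0);
    std::unordered_map<int, char> mark; mark[t0] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      bad.push_back(t);
      for (int i = 0; i < 4; i++) {
        int nb = tets[t].nb[i];
        if (nb >= 0 && tets[nb].alive && !mark.count(nb) && inSphere(tets[nb], p)) {
          mark[nb] = 1; stack.push_back(nb);
        }
      }
    }
    // cavity boundary faces: (face vertices, external tet, its slot)
    struct BFace { int a, b, c, ext, slot; };
    std::vector<BFace> bfaces;
    for (int t : bad) {
      for (int i = 0; i < 4; i++) {
        int nb = tets[t].nb[i];
        if (nb < 0 || !mark.count(nb)) {
          BFace f;
          f.a = tets[t].v[(i+1)&3]; f.b = tets[t].v[(i+2)&3]; f.c = tets[t].v[(i+3)&3];
          f.ext = nb; f.slot = -1;
          if (nb >= 0) for (int j = 0; j < 4; j++) if (tets[nb].nb[j] == t) f.slot = j;
          bfaces.push_back(f);
        }
      }
    }
    // cavity must be star-shaped and edge-valid: every edge of its boundary
    // belongs to exactly two boundary faces, else the retriangulation would
    // be corrupt (numerical insphere inconsistencies) -> caller retries
    {
      std::unordered_map<uint64_t, int> ec;
      for (auto &f : bfaces) {
        ec[edgeKey2(f.a, f.b)]++; ec[edgeKey2(f.b, f.c)]++; ec[edgeKey2(f.c, f.a)]++;
      }
      for (auto &kv : ec) if (kv.second != 2) return false;
    }
    // validate: each new tet must be well-oriented and non-degenerate
    std::vector<Tet> newTets(bfaces.size());
    for (size_t k = 0; k < bfaces.size(); k++) {
      Tet t; t.alive = true;
      t.v[0] = p; t.v[1] = bfaces[k].a; t.v[2] = bfaces[k].b; t.v[3] = bfaces[k].c;
      double o = orient(t.v[0], t.v[1], t.v[2], t.v[3]);
      if (o < 0) { std::swap(t.v[2], t.v[3]); o = -o; }
      if (o < ORIENT_EPS) return false;         // degenerate: caller retries
      if (!circum(t)) return false;
      newTets[k] = t;
    }
    // commit: kill bad tets, append new ones, wire neighbors
    for (int t : bad) tets[t].alive = false;
    int base = (int)tets.size();
    std::unordered_map<uint64_t, std::pair<int,int>> halffaces; // (u,v) edge of p-faces
    for (size_t k = 0; k < bfaces.size(); k++) {
      Tet &t = newTets[k];
      t.nb[0] = bfaces[k].ext;                  // opposite p = external tet
      if (bfaces[k].ext >= 0 && bfaces[k].slot >= 0)
        tets[bfaces[k].ext].nb[bfaces[k].slot] = base + (int)k;
      t.nb[1] = t.nb[2] = t.nb[3] = -1;
      tets.push_back(t);
    }
    // wire internal faces (p, x, y) shared by two new tets
    for (size_t k = 0; k < bfaces.size(); k++) {
      Tet &t = tets[base + k];
      for (int i = 1; i < 4; i++) {
        int x = t.v[(i==1)?2:1], y = t.v[(i==3)?2:3];
        // face opposite v[i] contains p and the two remaining vertices
        int others[2], m = 0;
        for (int j = 1; j < 4; j++) if (j != i) others[m++] = t.v[j];
        uint64_t key = others[0] < others[1]
          ? ((uint64_t)others[0] << 32) | (uint64_t)others[1]
          : ((uint64_t)others[1] << 32) | (uint64_t)others[0];
        (void)x; (void)y;
        auto it = halffaces.find(key);
        if (it == halffaces.end()) {
          halffaces[key] = std::make_pair(base + (int)k, i);
        } else {
          int ot = it->second.first, oslot = it->second.second;
          t.nb[i] = ot;
          tets[ot].nb[oslot] = base + (int)k;
        }
      }
    }
    lastTet = base;
    return true;
  }
};

// [[Rcpp::export]]
List cpp_delaunay3d(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a tetrahedralization");
  // rescale to unit box
  double mn[3], mx[3];
  for (int j = 0; j < 3; j++) { mn[j] = R_PosInf; mx[j] = R_NegInf; }
  for (int i = 0; i < n; i++) for (int j = 0; j < 3; j++) {
    if (pts(i,j) < mn[j]) mn[j] = pts(i,j);
    if (pts(i,j) > mx[j]) mx[j] = pts(i,j);
  }
  double span = 0;
  for (int j = 0; j < 3; j++) span = std::max(span, mx[j]-mn[j]);
  if (span <= 0) stop("degenerate point cloud: zero spatial extent");
  Delaunay3D D;
  D.px.resize(n); D.py.resize(n); D.pz.resize(n);
  for (int i = 0; i < n; i++) {
    D.px[i] = (pts(i,0)-mn[0])/span;
    D.py[i] = (pts(i,1)-mn[1])/span;
    D.pz[i] = (pts(i,2)-mn[2])/span;
  }
  D.init(n);
  for (int i = 0; i < n; i++) {
    bool ok = D.insert(i);
    int tries = 0;
    double ox = D.px[i], oy = D.py[i], oz = D.pz[i];
    while (!ok && tries < 8) {
      // deterministic symbolic-style perturbation for degenerate inputs
      tries++;
      double h = 1e-10 * std::pow(10.0, tries) * (1 + (i % 97) / 97.0);
      D.px[i] = ox + h * (1 + ((i * 2654435761u) % 1000) / 1000.0);
      D.py[i] = oy + h * (1 + ((i * 40503u) % 1000) / 1000.0);
      D.pz[i] = oz + h * (1 + ((i * 9973u) % 1000) / 1000.0);
      ok = D.insert(i);
    }
    if (!ok) stop("Delaunay insertion failed for point %d (degenerate configuration)", i + 1);
  }
  // collect real tets, compute circumradii in original coordinates
  std::vector<std::array<int,4>> keep;
  for (const Tet &t : D.tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    keep.push_back({t.v[0], t.v[1], t.v[2], t.v[3]});
  }
  int m = (int)keep.size();
  IntegerMatrix tets(m, 4);
  NumericVector radii(m);
  for (int k = 0; k < m; k++) {
    for (int j = 0; j < 4; j++) tets(k, j) = keep[k][j] + 1;
    // circumradius from original coords
    int a=keep[k][0], b=keep[k][1], c=keep[k][2], d=keep[k][3];
    double ax=pts(a,0), ay=pts(a,1), az=pts(a,2);
    double bax=pts(b,0)-ax, bay=pts(b,1)-ay, baz=pts(b,2)-az;
    double cax=pts(c,0)-ax, cay=pts(c,1)-ay, caz=pts(c,2)-az;
    double dax=pts(d,0)-ax, day=pts(d,1)-ay, daz=pts(d,2)-az;
    double b2=bax*bax+bay*bay+baz*baz;
    double c2=cax*cax+cay*cay+caz*caz;
    double d2=dax*dax+day*day+daz*daz;
    double det = bax*(cay*daz-caz*day) - bay*(cax*daz-caz*dax) + baz*(cax*day-cay*dax);
    if (std::fabs(det) < 1e-300) { radii[k] = R_PosInf; continue; }
    double ox = (b2*(cay*daz-caz*day) - bay*(c2*daz-d2*caz) + baz*(c2*day-d2*cay)) / (2*det);
    double oy = (bax*(c2*daz-d2*caz) - b2*(cax*daz-caz*dax) + baz*(cax*d2-c2*dax)) / (2*det);
    double oz = (bax*(cay*d2-c2*day) - bay*(cax*d2-c2*dax) + b2*(cax*day-cay*dax)) / (2*det);
    radii[k] = std::sqrt(ox*ox+oy*oy+oz*oz);
  }
  return List::create(_["tets"] = tets, _["circumradius"] = radii);
}

// ---------------------------------------------------------------- 2D engine

struct Tri {
  int v[3];
  int nb[3];
  bool alive;
  double cc[2];
  double r2;
};

class Delaunay2D {
public:
  std::vector<double> px, py;
  std::vector<Tri> tris;
  int n, lastTri;

  double orient(int a, int b, int c) const {
    return (px[b]-px[a])*(py[c]-py[a]) - (py[b]-py[a])*(px[c]-px[a]);
  }
  bool circum(Tri &t) {
    int a=t.v[0], b=t.v[1], c=t.v[2];
    double bax=px[b]-px[a], bay=py[b]-py[a];
    double cax=px[c]-px[a], cay=py[c]-py[a];
    double b2=bax*bax+bay*bay, c2=cax*cax+cay*cay;
    double det = 2*(bax*cay - bay*cax);
    if (std::fabs(det) < 1e-300) return false;
    double ox = (cay*b2 - bay*c2)/det, oy = (bax*c2 - cax*b2)/det;
    t.cc[0]=px[a]+ox; t.cc[1]=py[a]+oy;
    t.r2 = ox*ox+oy*oy;
    return true;
  }
  bool inCircle(const Tri &t, int p) const {
    double dx=px[p]-t.cc[0], dy=py[p]-t.cc[1];
    return dx*dx+dy*dy < t.r2 * (1.0 + 1e-12);
  }
  void init(int npts) {
    n = npts;
    double R = 1e4;
    px.push_back(0.5);      py.push_back(0.5 + R);
    px.push_back(0.5 + R);  py.push_back(0.5 - R);
    px.push_back(0.5 - R);  py.push_back(0.5 - R * 1.0002);
    Tri t; t.alive = true;
    t.v[0]=n; t.v[1]=n+1; t.v[2]=n+2;
    if (orient(t.v[0],t.v[1],t.v[2]) < 0) std::swap(t.v[1], t.v[2]);
    t.nb[0]=t.nb[1]=t.nb[2]=-1;
    circum(t);
    tris.push_back(t);
    lastTri = 0;
  }
  int locate(int p) {
    int cur = lastTri;
    if (cur < 0 || !tris[cur].alive) {
      for (int i = (int)tris.size()-1; i >= 0; i--) if (tris[i].alive) { cur = i; break; }
    }
    int steps = 0, maxSteps = (int)tris.size() * 3 + 64;
    while (steps++ < maxSteps) {
      const Tri &t = tris[cur];
      int next = -1;
      for (int i = 0; i < 3; i++) {
        int a = t.v[(i+1)%3], b = t.v[(i+2)%3];
        double op = orient(a, b, t.v[i]);
        double oq = orient(a, b, p);
        if (op * oq < -ORIENT_EPS && t.nb[i] >= 0) { next = t.nb[i]; break; }
      }
      if (next < 0) return cur;
      cur = next;
    }
    for (int i = 0; i < (int)tris.size(); i++)
      if (tris[i].alive && inCircle(tris[i], p)) return i;
    return cur;
  }
  bool insert(int p) {
    int t0 = locate(p);
    if (!inCircle(tris[t0], p)) {
      bool found = false;
      for (int i = 0; i < 3 && !found; i++) {
        int nb = tris[t0].nb[i];
        if (nb >= 0 && tris[nb].alive && inCircle(tris[nb], p)) { t0 = nb; found = true; }
      }
      if (!found) {
        for (int i = (int)tris.size() - 1; i >= 0; i--)
          if (tris[i].alive && inCircle(tris[i], p)) { t0 = i; found = true; break; }
      }
      if (!found) return false;
    }
    std::vector<int> bad, stack; stack.push_back(t0);
    std::unordered_map<int,char> mark; mark[t0]=1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      bad.push_back(t);
      for (int i = 0; i < 3; i++) {
        int nb = tris[t].nb[i];
        if (nb >= 0 && tris[nb].alive && !mark.count(nb) && inCircle(tris[nb], p)) {
          mark[nb]=1; stack.push_back(nb);
        }
      }
    }
    struct BEdge { int a, b, ext, slot; };
    std::vector<BEdge> bedges;
    for (int t : bad) for (int i = 0; i < 3; i++) {
      int nb = tris[t].nb[i];
      if (nb < 0 || !mark.count(nb)) {
        BEdge e; e.a = tris[t].v[(i+1)%3]; e.b = tris[t].v[(i+2)%3];
        e.ext = nb; e.slot = -1;
        if (nb >= 0) for (int j = 0; j < 3; j++) if (tris[nb].nb[j] == t) e.slot = j;
        bedges.push_back(e);
      }
    }
    // cavity boundary must be a simple closed polygon: every vertex on it
    // appears in exactly two boundary edges, else retriangulation corrupts
    {
      std::unordered_map<int, int> vc;
      for (auto &e : bedges) { vc[e.a]++; vc[e.b]++; }
      for (auto &kv : vc) if (kv.second != 2) return false;
    }
    std::vector<Tri> newTris(bedges.size());
    for (size_t k = 0; k < bedges.size(); k++) {
      Tri t; t.alive = true;
      t.v[0] = p; t.v[1] = bedges[k].a; t.v[2] = bedges[k].b;
      double o = orient(t.v[0], t.v[1], t.v[2]);
      if (o < 0) { std::swap(t.v[1], t.v[2]); o = -o; }
      if (o < ORIENT_EPS) return false;
      if (!circum(t)) return false;
      newTris[k] = t;
    }
    for (int t : bad) tris[t].alive = false;
    int base = (int)tris.size();
    std::unordered_map<int, std::pair<int,int>> halfedges;
    for (size_t k = 0; k < bedges.size(); k++) {
      Tri &t = newTris[k];
      t.nb[0] = bedges[k].ext;
      if (bedges[k].ext >= 0 && bedges[k].slot >= 0)
        tris[bedges[k].ext].nb[bedges[k].slot] = base + (int)k;
      t.nb[1] = t.nb[2] = -1;
      tris.push_back(t);
    }
    for (size_t k = 0; k < bedges.size(); k++) {
      Tri &t = tris[base + k];
      for (int i = 1; i < 3; i++) {
        int other = t.v[(i==1) ? 2 : 1];
        auto it = halfedges.find(other);
        if (it == halfedges.end()) halfedges[other] = std::make_pair(base+(int)k, i);
        else {
          t.nb[i] = it->second.first;
          tris[it->second.first].nb[it->second.second] = base + (int)k;
        }
      }
    }
    lastTri = base;
    return true;
  }
};

// [[Rcpp::export]]
List cpp_delaunay2d(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points for a triangulation");
  double mn[2] = {R_PosInf, R_PosInf}, mx[2] = {R_NegInf, R_NegInf};
  for (int i = 0; i < n; i++) for (int j = 0; j < 2; j++) {
    if (pts(i,j) < mn[j]) mn[j] = pts(i,j);
    if (pts(i,j) > mx[j]) mx[j] = pts(i,j);
  }
  double span = std::max(mx[0]-mn[0], mx[1]-mn[1]);
  if (span <= 0) stop("degenerate 2D point set: zero extent");
  Delaunay2D D;
  D.px.resize(n); D.py.resize(n);
  for (int i = 0; i < n; i++) {
    D.px[i] = (pts(i,0)-mn[0])/span;
    D.py[i] = (pts(i,1)-mn[1])/span;
  }
  D.init(n);
  for (int i = 0; i < n; i++) {
    bool ok = D.insert(i);
    int tries = 0;
    double ox = D.px[i], oy = D.py[i];
    while (!ok && tries < 8) {
      tries++;
      double h = 1e-10 * std::pow(10.0, tries) * (1 + (i % 97) / 97.0);
      D.px[i] = ox + h * (1 + ((i * 2654435761u) % 1000) / 1000.0);
      D.py[i] = oy + h * (1 + ((i * 40503u) % 1000) / 1000.0);
      ok = D.insert(i);
    }
    if (!ok) stop("Delaunay insertion failed for point %d (degenerate configuration)", i + 1);
  }
  std::vector<std::array<int,3>> keep;
  for (const Tri &t : D.tris) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n) continue;
    keep.push_back({t.v[0], t.v[1], t.v[2]});
  }
  int m = (int)keep.size();
  IntegerMatrix tris(m, 3);
  NumericVector radii(m);
  for (int k = 0; k < m; k++) {
    for (int j = 0; j < 3; j++) tris(k, j) = keep[k][j] + 1;
    int a=keep[k][0], b=keep[k][1], c=keep[k][2];
    double bax=pts(b,0)-pts(a,0), bay=pts(b,1)-pts(a,1);
    double cax=pts(c,0)-pts(a,0), cay=pts(c,1)-pts(a,1);
    double b2=bax*bax+bay*bay, c2=cax*cax+cay*cay;
    double det = 2*(bax*cay - bay*cax);
    if (std::fabs(det) < 1e-300) { radii[k] = R_PosInf; continue; }
    double ox = (cay*b2 - bay*c2)/det, oy = (bax*c2 - cax*b2)/det;
    radii[k] = std::sqrt(ox*ox+oy*oy);
  }
  return List::create(_["triangles"] = tris, _["circumradius"] = radii);
}

// ------------------------------------------------------- alpha boundary (3D)

static inline uint64_t faceKey(int a, int b, int c) {
  int x = a, y = b, z = c;
  if (x > y) std::swap(x, y);
  if (y > z) std::swap(y, z);
  if (x > y) std::swap(x, y);
  return ((uint64_t)x << 42) | ((uint64_t)y << 21) | (uint64_t)z;
}
static inline uint64_t edgeKey(int a, int b) {
  return a < b ? (((uint64_t)a << 32) | (uint64_t)b) : (((uint64_t)b << 32) | (uint64_t)a);
}

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; i++) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { p[find(a)] = find(b); }
};

// Extract the boundary surface of the kept tetrahedra; test closure.
// Small disconnected surface components (< fracDrop of total area) are
// dropped before the closure test so that stray islands cannot block it.
// [[Rcpp::export]]
List cpp_alpha_boundary(IntegerMatrix tets, NumericMatrix pts, LogicalVector keep,
                        double fracDrop = 0.01) {
  int m = tets.nrow();
  std::unordered_map<uint64_t, int> count;
  std::unordered_map<uint64_t, std::pair<int,int>> owner; // tet idx, opposite slot
  count.reserve(m * 2);
  for (int k = 0; k < m; k++) {
    if (!keep[k]) continue;
    for (int i = 0; i < 4; i++) {
      int a = tets(k, (i+1)&3)-1, b = tets(k, (i+2)&3)-1, c = tets(k, (i+3)&3)-1;
      uint64_t key = faceKey(a, b, c);
      auto it = count.find(key);
      if (it == count.end()) { count[key] = 1; owner[key] = std::make_pair(k, i); }
      else it->second++;
    }
  }
  // boundary faces, oriented outward (normal away from opposite vertex)
  std::vector<std::array<int,3>> faces;
  for (auto &kv : count) {
    if (kv.second != 1) continue;
    int k = owner[kv.first].first, slot = owner[kv.first].second;
    int a = tets(k, (slot+1)&3)-1, b = tets(k, (slot+2)&3)-1, c = tets(k, (slot+3)&3)-1;
    int d = tets(k, slot)-1;
    double bax=pts(b,0)-pts(a,0), bay=pts(b,1)-pts(a,1), baz=pts(b,2)-pts(a,2);
    double cax=pts(c,0)-pts(a,0), cay=pts(c,1)-pts(a,1), caz=pts(c,2)-pts(a,2);
    double nx=bay*caz-baz*cay, ny=baz*cax-bax*caz, nz=bax*cay-bay*cax;
    double dax=pts(d,0)-pts(a,0), day=pts(d,1)-pts(a,1), daz=pts(d,2)-pts(a,2);
    if (nx*dax+ny*day+nz*daz > 0) faces.push_back({a, c, b});
    else faces.push_back({a, b, c});
  }
  int nf = (int)faces.size();
  if (nf == 0) {
    return List::create(_["closed"] = false, _["volume"] = 0.0,
                        _["faces"] = IntegerMatrix(0, 3),
                        _["badEdges"] = 0, _["nComponents"] = 0);
  }
  // connect faces sharing an edge; per-face area
  std::vector<double> area(nf);
  UF uf(nf);
  std::unordered_map<uint64_t, int> edgeFirst;
  std::unordered_map<uint64_t, int> edgeCount;
  for (int f = 0; f < nf; f++) {
    int a = faces[f][0], b = faces[f][1], c = faces[f][2];
    double bax=pts(b,0)-pts(a,0), bay=pts(b,1)-pts(a,1), baz=pts(b,2)-pts(a,2);
    double cax=pts(c,0)-pts(a,0), cay=pts(c,1)-pts(a,1), caz=pts(c,2)-pts(a,2);
    double nx=bay*caz-baz*cay, ny=baz*cax-bax*caz, nz=bax*cay-bay*cax;
    area[f] = 0.5*std::sqrt(nx*nx+ny*ny+nz*nz);
    int e[3][2] = {{a,b},{b,c},{c,a}};
    for (int i = 0; i < 3; i++) {
      uint64_t key = edgeKey(e[i][0], e[i][1]);
      edgeCount[key]++;
      auto it = edgeFirst.find(key);
      if (it == edgeFirst.end()) edgeFirst[key] = f;
      else uf.unite(f, it->second);
    }
  }
  // component areas
  std::unordered_map<int,double> compArea;
  double totArea = 0;
  for (int f = 0; f < nf; f++) { compArea[uf.find(f)] += area[f]; totArea += area[f]; }
  // keep components with area >= fracDrop * total
  std::unordered_map<int,char> keepComp;
  int nComp = 0;
  for (auto &kv : compArea) {
    nComp++;
    if (kv.second >= fracDrop * totArea) keepComp[kv.first] = 1;
  }
  std::vector<int> keptFaces;
  for (int f = 0; f < nf; f++) if (keepComp.count(uf.find(f))) keptFaces.push_back(f);
  // manifold check on kept faces
  std::unordered_map<uint64_t,int> ec2;
  for (int f : keptFaces) {
    int a = faces[f][0], b = faces[f][1], c = faces[f][2];
    ec2[edgeKey(a,b)]++; ec2[edgeKey(b,c)]++; ec2[edgeKey(c,a)]++;
  }
  int bad = 0;
  for (auto &kv : ec2) if (kv.second != 2) bad++;
  // single enclosing component requirement: exactly one kept component
  int keptComps = (int)keepComp.size();
  // signed volume via divergence theorem over kept faces
  double vol6 = 0;
  for (int f : keptFaces) {
    int a = faces[f][0], b = faces[f][1], c = faces[f][2];
    double ax=pts(a,0), ay=pts(a,1), az=pts(a,2);
    double bx=pts(b,0), by=pts(b,1), bz=pts(b,2);
    double cx=pts(c,0), cy=pts(c,1), cz=pts(c,2);
    vol6 += ax*(by*cz-bz*cy) - ay*(bx*cz-bz*cx) + az*(bx*cy-by*cx);
  }
  double volume = std::fabs(vol6) / 6.0;
  bool closed = (bad == 0) && (keptComps == 1) && (volume > 0) && !keptFaces.empty();
  IntegerMatrix outFaces((int)keptFaces.size(), 3);
  for (size_t i = 0; i < keptFaces.size(); i++)
    for (int j = 0; j < 3; j++) outFaces((int)i, j) = faces[keptFaces[i]][j] + 1;
  return List::create(_["closed"] = closed, _["volume"] = volume,
                      _["faces"] = outFaces, _["badEdges"] = bad,
                      _["nComponents"] = keptComps);
}

// Edge audit of an arbitrary triangle mesh: returns the number of edges not
// shared by exactly two triangles (0 for a closed edge-manifold surface).
// [[Rcpp::export]]
int cpp_mesh_bad_edges(IntegerMatrix tris) {
  std::unordered_map<uint64_t,int> ec;
  for (int k = 0; k < tris.nrow(); k++) {
    int a = tris(k,0)-1, b = tris(k,1)-1, c = tris(k,2)-1;
    ec[edgeKey(a,b)]++; ec[edgeKey(b,c)]++; ec[edgeKey(c,a)]++;
  }
  int bad = 0;
  for (auto &kv : ec) if (kv.second != 2) bad++;
  return bad;
}

// ------------------------------------------------ 2D alpha complex raster

// Which cells of a uniform grid have their center covered by at least one of
// the given triangles (inclusive of edges)?
// Grid cell (ix, iy), 0-based; center = origin + (i + 0.5) * vs.
// [[Rcpp::export]]
LogicalVector cpp_cover_cells(NumericMatrix pts, IntegerMatrix tris,
                              NumericVector origin, double vs, int nx, int ny) {
  LogicalVector cov(nx * ny);
  double eps = 1e-12;
  for (int k = 0; k < tris.nrow(); k++) {
    int a = tris(k,0)-1, b = tris(k,1)-1, c = tris(k,2)-1;
    double ax=pts(a,0), ay=pts(a,1), bx=pts(b,0), by=pts(b,1), cx=pts(c,0), cy=pts(c,1);
    double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::floor((xmin - origin[0]) / vs - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((xmax - origin[0]) / vs));
    int j0 = std::max(0, (int)std::floor((ymin - origin[1]) / vs - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - origin[1]) / vs));
    double d = (bx-ax)*(cy-ay) - (by-ay)*(cx-ax);
    if (std::fabs(d) < 1e-300) continue;
    double tol = eps * std::fabs(d) + 1e-300;
    for (int i = i0; i <= i1; i++) {
      double x = origin[0] + (i + 0.5) * vs;
      for (int j = j0; j <= j1; j++) {
        if (cov[i + (int64_t)j * nx]) continue;
        double y = origin[1] + (j + 0.5) * vs;
        double w0 = ((bx-x)*(cy-y) - (by-y)*(cx-x));
        double w1 = ((cx-x)*(ay-y) - (cy-y)*(ax-x));
        double w2 = ((ax-x)*(by-y) - (ay-y)*(bx-x));
        if (d > 0) {
          if (w0 >= -tol && w1 >= -tol && w2 >= -tol) cov[i + (int64_t)j * nx] = true;
        } else {
          if (w0 <= tol && w1 <= tol && w2 <= tol) cov[i + (int64_t)j * nx] = true;
        }
      }
    }
  }
  return cov;
}
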