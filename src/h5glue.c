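/* Minimal HDF5 glue for neurofmt.
 *
 * Conventions:
 *  - All entry points open the file, act, and close it; no handles cross the
 *    R/C boundary.  Files here are small enough that this is not a bottleneck.
 *  - R dim vectors are reported / accepted in R (column-major) order; HDF5
 *    dims on disk are the reverse, so the memory layout needs no transpose.
 *  - Indices at this layer are 0-based (HDF5 native); R wrappers convert.
 */

#include <R.h>
#include <Rinternals.h>
#include <hdf5.h>
#include <hdf5_hl.h>
#include <string.h>
#include <stdlib.h>

/* ---- helpers ---------------------------------------------------------- */

static void silence_errors(void)
{
    H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
}

static hid_t open_file(const char *path, int readonly)
{
    silence_errors();
    hid_t f = H5Fopen(path, readonly ? H5F_ACC_RDONLY : H5F_ACC_RDWR,
                      H5P_DEFAULT);
    if (f < 0)
        Rf_error("cannot open HDF5 file '%s'", path);
    return f;
}

#define CHK(expr, fid, msg) do {                                   \
        if ((expr) < 0) { if ((fid) >= 0) H5Fclose(fid);           \
            Rf_error("HDF5 error: %s", (msg)); }                   \
    } while (0)

/* reverse an R dim vector into an hsize_t array (caller frees) */
static hsize_t *rev_dims(SEXP rdims, int *rank)
{
    int n = LENGTH(rdims);
    hsize_t *d = (hsize_t *) R_alloc(n, sizeof(hsize_t));
    double *v = REAL(rdims);
    for (int i = 0; i < n; i++)
        d[i] = (hsize_t) v[n - 1 - i];
    *rank = n;
    return d;
}

/* ---- file / group ----------------------------------------------------- */

SEXP C_h5_file_create(SEXP path, SEXP overwrite)
{
    silence_errors();
    const char *p = CHAR(STRING_ELT(path, 0));
    unsigned flags = LOGICAL(overwrite)[0] ? H5F_ACC_TRUNC : H5F_ACC_EXCL;
    hid_t f = H5Fcreate(p, flags, H5P_DEFAULT, H5P_DEFAULT);
    if (f < 0)
        Rf_error("cannot create HDF5 file '%s' (exists?)", p);
    H5Fclose(f);
    return R_NilValue;
}

SEXP C_h5_is_hdf5(SEXP path)
{
    silence_errors();
    htri_t r = H5Fis_accessible(CHAR(STRING_ELT(path, 0)), H5P_DEFAULT);
    return Rf_ScalarLogical(r > 0);
}

SEXP C_h5_group_create(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    hid_t lcpl = H5Pcreate(H5P_LINK_CREATE);
    H5Pset_create_intermediate_group(lcpl, 1);
    hid_t g = H5Gcreate2(f, CHAR(STRING_ELT(path, 0)), lcpl,
                         H5P_DEFAULT, H5P_DEFAULT);
    H5Pclose(lcpl);
    CHK(g, f, "group creation failed");
    H5Gclose(g);
    H5Fclose(f);
    return R_NilValue;
}

/* link exists (does not follow the link) */
SEXP C_h5_link_exists(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    const char *p = CHAR(STRING_ELT(path, 0));
    int ok = 1;
    if (strcmp(p, "/") != 0) {
        /* every intermediate component must exist */
        char *buf = (char *) R_alloc(strlen(p) + 1, 1);
        strcpy(buf, p);
        for (char *c = buf + 1; *c; c++) {
            if (*c == '/') {
                *c = '\0';
                if (H5Lexists(f, buf, H5P_DEFAULT) <= 0) { ok = 0; break; }
                *c = '/';
            }
        }
        if (ok)
            ok = H5Lexists(f, buf, H5P_DEFAULT) > 0;
    }
    H5Fclose(f);
    return Rf_ScalarLogical(ok);
}

/* object openable (follows links; FALSE for dangling external links) */
SEXP C_h5_object_exists(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    hid_t o = H5Oopen(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT);
    int ok = o >= 0;
    if (ok) H5Oclose(o);
    H5Fclose(f);
    return Rf_ScalarLogical(ok);
}

SEXP C_h5_obj_kind(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    hid_t o = H5Oopen(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT);
    const char *kind = "missing";
    if (o >= 0) {
        H5I_type_t t = H5Iget_type(o);
        kind = (t == H5I_GROUP) ? "group" :
               (t == H5I_DATASET) ? "dataset" : "other";
        H5Oclose(o);
    }
    H5Fclose(f);
    return Rf_mkString(kind);
}

SEXP C_h5_ls(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    hid_t g = H5Gopen2(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT);
    CHK(g, f, "cannot open group");
    H5G_info_t info;
    H5Gget_info(g, &info);
    SEXP out = PROTECT(Rf_allocVector(STRSXP, (int) info.nlinks));
    for (hsize_t i = 0; i < info.nlinks; i++) {
        ssize_t len = H5Lget_name_by_idx(g, ".", H5_INDEX_NAME, H5_ITER_INC,
                                         i, NULL, 0, H5P_DEFAULT);
        char *nm = (char *) R_alloc(len + 1, 1);
        H5Lget_name_by_idx(g, ".", H5_INDEX_NAME, H5_ITER_INC, i, nm,
                           len + 1, H5P_DEFAULT);
        SET_STRING_ELT(out, (int) i, Rf_mkCharCE(nm, CE_UTF8));
    }
    H5Gclose(g);
    H5Fclose(f);
    UNPROTECT(1);
    return out;
}

SEXP C_h5_link_kind(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    H5L_info2_t info;
    herr_t s = H5Lget_info2(f, CHAR(STRING_ELT(path, 0)), &info, H5P_DEFAULT);
    const char *kind = "missing";
    if (s >= 0)
        kind = (info.type == H5L_TYPE_EXTERNAL) ? "external" :
               (info.type == H5L_TYPE_SOFT) ? "soft" : "hard";
    H5Fclose(f);
    return Rf_mkString(kind);
}

SEXP C_h5_external_link_target(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    const char *p = CHAR(STRING_ELT(path, 0));
    H5L_info2_t info;
    CHK(H5Lget_info2(f, p, &info, H5P_DEFAULT), f, "no such link");
    if (info.type != H5L_TYPE_EXTERNAL) {
        H5Fclose(f);
        Rf_error("link is not external");
    }
    char *buf = (char *) R_alloc(info.u.val_size, 1);
    CHK(H5Lget_val(f, p, buf, info.u.val_size, H5P_DEFAULT), f,
        "cannot read link value");
    const char *tfile, *tpath;
    unsigned flags;
    CHK(H5Lunpack_elink_val(buf, info.u.val_size, &flags, &tfile, &tpath),
        f, "cannot unpack external link");
    SEXP out = PROTECT(Rf_allocVector(STRSXP, 2));
    SET_STRING_ELT(out, 0, Rf_mkCharCE(tfile, CE_UTF8));
    SET_STRING_ELT(out, 1, Rf_mkCharCE(tpath, CE_UTF8));
    H5Fclose(f);
    UNPROTECT(1);
    return out;
}

SEXP C_h5_create_external_link(SEXP file, SEXP linkpath, SEXP tfile, SEXP tpath)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    CHK(H5Lcreate_external(CHAR(STRING_ELT(tfile, 0)),
                           CHAR(STRING_ELT(tpath, 0)), f,
                           CHAR(STRING_ELT(linkpath, 0)),
                           H5P_DEFAULT, H5P_DEFAULT),
        f, "cannot create external link");
    H5Fclose(f);
    return R_NilValue;
}

SEXP C_h5_delete_link(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    CHK(H5Ldelete(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT), f,
        "cannot delete link");
    H5Fclose(f);
    return R_NilValue;
}

/* ---- datasets --------------------------------------------------------- */

SEXP C_h5_make_dataset(SEXP file, SEXP path, SEXP data, SEXP rdims,
                       SEXP unlimited, SEXP rchunks)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    int rank;
    hsize_t *dims = rev_dims(rdims, &rank);
    hsize_t *maxdims = (hsize_t *) R_alloc(rank, sizeof(hsize_t));
    int n = LENGTH(rdims);
    int any_unl = 0;
    for (int i = 0; i < rank; i++) {
        int unl = LOGICAL(unlimited)[n - 1 - i];
        maxdims[i] = unl ? H5S_UNLIMITED : dims[i];
        any_unl |= unl;
    }
    hid_t space = H5Screate_simple(rank, dims, maxdims);
    hid_t dcpl = H5Pcreate(H5P_DATASET_CREATE);
    if (any_unl || rchunks != R_NilValue) {
        hsize_t *ch;
        if (rchunks != R_NilValue) {
            int crank;
            ch = rev_dims(rchunks, &crank);
        } else {
            ch = (hsize_t *) R_alloc(rank, sizeof(hsize_t));
            for (int i = 0; i < rank; i++) {
                hsize_t c = dims[i] > 0 ? dims[i] : 1;
                if (maxdims[i] == H5S_UNLIMITED && c < 1024) c = 1024;
                if (c > 4096) c = 4096;
                ch[i] = c;
            }
        }
        H5Pset_chunk(dcpl, rank, ch);
    }
    hid_t dtype, mtype;
    if (TYPEOF(data) == REALSXP) {
        dtype = H5Tcopy(H5T_IEEE_F64LE);  mtype = H5T_NATIVE_DOUBLE;
    } else if (TYPEOF(data) == INTSXP) {
        dtype = H5Tcopy(H5T_STD_I32LE);   mtype = H5T_NATIVE_INT;
    } else if (TYPEOF(data) == STRSXP) {
        dtype = H5Tcopy(H5T_C_S1);
        H5Tset_size(dtype, H5T_VARIABLE);
        H5Tset_cset(dtype, H5T_CSET_UTF8);
        mtype = dtype;
    } else {
        H5Fclose(f);
        Rf_error("unsupported R type for HDF5 dataset");
    }
    hid_t d = H5Dcreate2(f, CHAR(STRING_ELT(path, 0)), dtype, space,
                         H5P_DEFAULT, dcpl, H5P_DEFAULT);
    if (d < 0) { H5Fclose(f); Rf_error("dataset creation failed at '%s'",
                                       CHAR(STRING_ELT(path, 0))); }
    hsize_t total = 1;
    for (int i = 0; i < rank; i++) total *= dims[i];
    if (total > 0) {
        if (TYPEOF(data) == REALSXP)
            H5Dwrite(d, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(data));
        else if (TYPEOF(data) == INTSXP)
            H5Dwrite(d, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, INTEGER(data));
        else {
            const char **buf = (const char **)
                R_alloc(LENGTH(data), sizeof(char *));
            for (int i = 0; i < LENGTH(data); i++)
                buf[i] = Rf_translateCharUTF8(STRING_ELT(data, i));
            H5Dwrite(d, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf);
        }
    }
    H5Tclose(dtype);
    H5Pclose(dcpl);
    H5Sclose(space);
    H5Dclose(d);
    H5Fclose(f);
    return R_NilValue;
}

SEXP C_h5_dataset_dims(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    hid_t d = H5Dopen2(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT);
    CHK(d, f, "cannot open dataset");
    hid_t space = H5Dget_space(d);
    int rank = H5Sget_simple_extent_ndims(space);
    hsize_t *dims = (hsize_t *) R_alloc(rank > 0 ? rank : 1, sizeof(hsize_t));
    H5Sget_simple_extent_dims(space, dims, NULL);
    SEXP out = PROTECT(Rf_allocVector(REALSXP, rank));
    for (int i = 0; i < rank; i++)
        REAL(out)[i] = (double) dims[rank - 1 - i];   /* back to R order */
    H5Sclose(space);
    H5Dclose(d);
    H5Fclose(f);
    UNPROTECT(1);
    return out;
}

SEXP C_h5_read_dataset(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    hid_t d = H5Dopen2(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT);
    CHK(d, f, "cannot open dataset");
    hid_t space = H5Dget_space(d);
    int rank = H5Sget_simple_extent_ndims(space);
    hsize_t dims[32];
    H5Sget_simple_extent_dims(space, dims, NULL);
    R_xlen_t total = 1;
    for (int i = 0; i < rank; i++) total *= (R_xlen_t) dims[i];
    hid_t dtype = H5Dget_type(d);
    H5T_class_t cls = H5Tget_class(dtype);
    SEXP out;
    if (cls == H5T_FLOAT) {
        out = PROTECT(Rf_allocVector(REALSXP, total));
        if (total > 0)
            H5Dread(d, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    REAL(out));
    } else if (cls == H5T_INTEGER) {
        out = PROTECT(Rf_allocVector(INTSXP, total));
        if (total > 0)
            H5Dread(d, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    INTEGER(out));
    } else if (cls == H5T_STRING) {
        out = PROTECT(Rf_allocVector(STRSXP, total));
        if (total > 0) {
            hid_t mt = H5Tcopy(H5T_C_S1);
            H5Tset_size(mt, H5T_VARIABLE);
            H5Tset_cset(mt, H5T_CSET_UTF8);
            char **buf = (char **) R_alloc(total, sizeof(char *));
            H5Dread(d, mt, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf);
            for (R_xlen_t i = 0; i < total; i++)
                SET_STRING_ELT(out, i, Rf_mkCharCE(buf[i], CE_UTF8));
            H5Dvlen_reclaim(mt, space, H5P_DEFAULT, buf);
            H5Tclose(mt);
        }
    } else {
        H5Tclose(dtype); H5Sclose(space); H5Dclose(d); H5Fclose(f);
        Rf_error("unsupported dataset type class");
    }
    if (rank > 1) {
        SEXP rd = PROTECT(Rf_allocVector(INTSXP, rank));
        for (int i = 0; i < rank; i++)
            INTEGER(rd)[i] = (int) dims[rank - 1 - i];
        Rf_setAttrib(out, R_DimSymbol, rd);
        UNPROTECT(1);
    }
    H5Tclose(dtype);
    H5Sclose(space);
    H5Dclose(d);
    H5Fclose(f);
    UNPROTECT(1);
    return out;
}

SEXP C_h5_set_extent(SEXP file, SEXP path, SEXP rdims)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    hid_t d = H5Dopen2(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT);
    CHK(d, f, "cannot open dataset");
    int rank;
    hsize_t *dims = rev_dims(rdims, &rank);
    herr_t s = H5Dset_extent(d, dims);
    H5Dclose(d);
    CHK(s, f, "set_extent failed (dataset not extendible?)");
    H5Fclose(f);
    return R_NilValue;
}

/* write a hyperslab; start/count given in R order, start 0-based */
SEXP C_h5_write_hyperslab(SEXP file, SEXP path, SEXP data, SEXP rstart,
                          SEXP rcount)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    hid_t d = H5Dopen2(f, CHAR(STRING_ELT(path, 0)), H5P_DEFAULT);
    CHK(d, f, "cannot open dataset");
    int rank;
    hsize_t *start = rev_dims(rstart, &rank);
    hsize_t *count = rev_dims(rcount, &rank);
    hid_t fspace = H5Dget_space(d);
    herr_t s = H5Sselect_hyperslab(fspace, H5S_SELECT_SET, start, NULL,
                                   count, NULL);
    if (s < 0) { H5Dclose(d); H5Fclose(f); Rf_error("hyperslab selection failed"); }
    hid_t mspace = H5Screate_simple(rank, count, NULL);
    if (TYPEOF(data) == REALSXP)
        s = H5Dwrite(d, H5T_NATIVE_DOUBLE, mspace, fspace, H5P_DEFAULT,
                     REAL(data));
    else if (TYPEOF(data) == INTSXP)
        s = H5Dwrite(d, H5T_NATIVE_INT, mspace, fspace, H5P_DEFAULT,
                     INTEGER(data));
    else
        s = -1;
    H5Sclose(mspace);
    H5Sclose(fspace);
    H5Dclose(d);
    CHK(s, f, "hyperslab write failed");
    H5Fclose(f);
    return R_NilValue;
}

/* ---- attributes -------------------------------------------------------- */

static hid_t open_obj(hid_t f, const char *path)
{
    hid_t o = H5Oopen(f, path, H5P_DEFAULT);
    if (o < 0) { H5Fclose(f); Rf_error("cannot open object '%s'", path); }
    return o;
}

SEXP C_h5_write_attr(SEXP file, SEXP path, SEXP name, SEXP value)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    hid_t o = open_obj(f, CHAR(STRING_ELT(path, 0)));
    const char *nm = CHAR(STRING_ELT(name, 0));
    if (H5Aexists(o, nm) > 0)
        H5Adelete(o, nm);
    hsize_t n = (hsize_t) XLENGTH(value);
    hid_t space = (n == 1) ? H5Screate(H5S_SCALAR)
                           : H5Screate_simple(1, &n, NULL);
    herr_t s = -1;
    if (TYPEOF(value) == STRSXP) {
        hid_t t = H5Tcopy(H5T_C_S1);
        H5Tset_size(t, H5T_VARIABLE);
        H5Tset_cset(t, H5T_CSET_UTF8);
        hid_t a = H5Acreate2(o, nm, t, space, H5P_DEFAULT, H5P_DEFAULT);
        if (a >= 0) {
            const char **buf = (const char **) R_alloc(n, sizeof(char *));
            for (hsize_t i = 0; i < n; i++)
                buf[i] = Rf_translateCharUTF8(STRING_ELT(value, i));
            s = H5Awrite(a, t, buf);
            H5Aclose(a);
        }
        H5Tclose(t);
    } else if (TYPEOF(value) == REALSXP) {
        hid_t a = H5Acreate2(o, nm, H5T_IEEE_F64LE, space, H5P_DEFAULT,
                             H5P_DEFAULT);
        if (a >= 0) { s = H5Awrite(a, H5T_NATIVE_DOUBLE, REAL(value));
                      H5Aclose(a); }
    } else if (TYPEOF(value) == INTSXP) {
        hid_t a = H5Acreate2(o, nm, H5T_STD_I32LE, space, H5P_DEFAULT,
                             H5P_DEFAULT);
        if (a >= 0) { s = H5Awrite(a, H5T_NATIVE_INT, INTEGER(value));
                      H5Aclose(a); }
    }
    H5Sclose(space);
    H5Oclose(o);
    CHK(s, f, "attribute write failed");
    H5Fclose(f);
    return R_NilValue;
}

SEXP C_h5_read_attr(SEXP file, SEXP path, SEXP name)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    hid_t o = open_obj(f, CHAR(STRING_ELT(path, 0)));
    const char *nm = CHAR(STRING_ELT(name, 0));
    hid_t a = H5Aopen(o, nm, H5P_DEFAULT);
    if (a < 0) { H5Oclose(o); H5Fclose(f);
                 Rf_error("no attribute '%s'", nm); }
    hid_t space = H5Aget_space(a);
    hssize_t total = H5Sget_simple_extent_npoints(space);
    hid_t t = H5Aget_type(a);
    H5T_class_t cls = H5Tget_class(t);
    SEXP out = R_NilValue;
    if (cls == H5T_STRING) {
        out = PROTECT(Rf_allocVector(STRSXP, total));
        hid_t mt = H5Tcopy(H5T_C_S1);
        H5T_cset_t cset = H5Tget_cset(t);   /* no ASCII<->UTF8 conversion */
        if (H5Tis_variable_str(t)) {
            H5Tset_size(mt, H5T_VARIABLE);
            H5Tset_cset(mt, cset);
            char **buf = (char **) R_alloc(total, sizeof(char *));
            H5Aread(a, mt, buf);
            for (hssize_t i = 0; i < total; i++)
                SET_STRING_ELT(out, i, Rf_mkCharCE(buf[i], CE_UTF8));
            /* vlen strings from H5Aread must be freed */
            for (hssize_t i = 0; i < total; i++) free(buf[i]);
        } else {
            size_t sz = H5Tget_size(t);
            H5Tset_size(mt, sz + 1);
            H5Tset_cset(mt, cset);
            char *buf = (char *) R_alloc(total * (sz + 1), 1);
            memset(buf, 0, total * (sz + 1));
            H5Aread(a, mt, buf);
            for (hssize_t i = 0; i < total; i++)
                SET_STRING_ELT(out, i,
                               Rf_mkCharCE(buf + i * (sz + 1), CE_UTF8));
        }
        H5Tclose(mt);
    } else if (cls == H5T_FLOAT) {
        out = PROTECT(Rf_allocVector(REALSXP, total));
        H5Aread(a, H5T_NATIVE_DOUBLE, REAL(out));
    } else if (cls == H5T_INTEGER) {
        out = PROTECT(Rf_allocVector(INTSXP, total));
        H5Aread(a, H5T_NATIVE_INT, INTEGER(out));
    } else {
        H5Tclose(t); H5Sclose(space); H5Aclose(a); H5Oclose(o); H5Fclose(f);
        Rf_error("unsupported attribute type");
    }
    H5Tclose(t);
    H5Sclose(space);
    H5Aclose(a);
    H5Oclose(o);
    H5Fclose(f);
    UNPROTECT(1);
    return out;
}

SEXP C_h5_attr_exists(SEXP file, SEXP path, SEXP name)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    hid_t o = open_obj(f, CHAR(STRING_ELT(path, 0)));
    htri_t r = H5Aexists(o, CHAR(STRING_ELT(name, 0)));
    H5Oclose(o);
    H5Fclose(f);
    return Rf_ScalarLogical(r > 0);
}

SEXP C_h5_attr_delete(SEXP file, SEXP path, SEXP name)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    hid_t o = open_obj(f, CHAR(STRING_ELT(path, 0)));
    herr_t s = H5Adelete(o, CHAR(STRING_ELT(name, 0)));
    H5Oclose(o);
    CHK(s, f, "cannot delete attribute");
    H5Fclose(f);
    return R_NilValue;
}

static herr_t attr_name_cb(hid_t loc, const char *name,
                           const H5A_info_t *info, void *op_data)
{
    SEXP *acc = (SEXP *) op_data;
    R_xlen_t n = XLENGTH(*acc);
    SEXP bigger = PROTECT(Rf_allocVector(STRSXP, n + 1));
    for (R_xlen_t i = 0; i < n; i++)
        SET_STRING_ELT(bigger, i, STRING_ELT(*acc, i));
    SET_STRING_ELT(bigger, n, Rf_mkCharCE(name, CE_UTF8));
    R_ReleaseObject(*acc);
    R_PreserveObject(bigger);
    *acc = bigger;
    UNPROTECT(1);
    return 0;
}

SEXP C_h5_ls_attrs(SEXP file, SEXP path)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    hid_t o = open_obj(f, CHAR(STRING_ELT(path, 0)));
    SEXP acc = Rf_allocVector(STRSXP, 0);
    R_PreserveObject(acc);
    hsize_t idx = 0;
    H5Aiterate2(o, H5_INDEX_NAME, H5_ITER_INC, &idx, attr_name_cb, &acc);
    H5Oclose(o);
    H5Fclose(f);
    R_ReleaseObject(acc);
    return acc;
}

/* ---- dimension scales -------------------------------------------------- */

SEXP C_h5_ds_set_scale(SEXP file, SEXP dspath, SEXP name)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    hid_t d = H5Dopen2(f, CHAR(STRING_ELT(dspath, 0)), H5P_DEFAULT);
    CHK(d, f, "cannot open scale dataset");
    herr_t s = H5DSset_scale(d, CHAR(STRING_ELT(name, 0)));
    H5Dclose(d);
    CHK(s, f, "H5DSset_scale failed");
    H5Fclose(f);
    return R_NilValue;
}

/* axis given in R order (0-based); converted to HDF5 dim index */
static unsigned h5_axis(hid_t data, int r_axis, hid_t f)
{
    hid_t space = H5Dget_space(data);
    int rank = H5Sget_simple_extent_ndims(space);
    H5Sclose(space);
    if (r_axis < 0 || r_axis >= rank) {
        H5Dclose(data); H5Fclose(f);
        Rf_error("axis out of range");
    }
    return (unsigned) (rank - 1 - r_axis);
}

SEXP C_h5_ds_attach(SEXP file, SEXP dspath, SEXP datapath, SEXP axis)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 0);
    hid_t sc = H5Dopen2(f, CHAR(STRING_ELT(dspath, 0)), H5P_DEFAULT);
    CHK(sc, f, "cannot open scale dataset");
    hid_t da = H5Dopen2(f, CHAR(STRING_ELT(datapath, 0)), H5P_DEFAULT);
    if (da < 0) { H5Dclose(sc); H5Fclose(f); Rf_error("cannot open dataset"); }
    unsigned dim = h5_axis(da, INTEGER(axis)[0], f);
    herr_t s = H5DSattach_scale(da, sc, dim);
    H5Dclose(da);
    H5Dclose(sc);
    CHK(s, f, "H5DSattach_scale failed");
    H5Fclose(f);
    return R_NilValue;
}

SEXP C_h5_ds_is_attached(SEXP file, SEXP dspath, SEXP datapath, SEXP axis)
{
    hid_t f = open_file(CHAR(STRING_ELT(file, 0)), 1);
    hid_t sc = H5Dopen2(f, CHAR(STRING_ELT(dspath, 0)), H5P_DEFAULT);
    CHK(sc, f, "cannot open scale dataset");
    hid_t da = H5Dopen2(f, CHAR(STRING_ELT(datapath, 0)), H5P_DEFAULT);
    if (da < 0) { H5Dclose(sc); H5Fclose(f); Rf_error("cannot open dataset"); }
    unsigned dim = h5_axis(da, INTEGER(axis)[0], f);
    htri_t r = H5DSis_attached(da, sc, dim);
    H5Dclose(da);
    H5Dclose(sc);
    H5Fclose(f);
    return Rf_ScalarLogical(r > 0);
}

/* ---- registration ------------------------------------------------------ */

static const R_CallMethodDef CallEntries[] = {
    {"C_h5_file_create",          (DL_FUNC) &C_h5_file_create,          2},
    {"C_h5_is_hdf5",              (DL_FUNC) &C_h5_is_hdf5,              1},
    {"C_h5_group_create",         (DL_FUNC) &C_h5_group_create,         2},
    {"C_h5_link_exists",          (DL_FUNC) &C_h5_link_exists,          2},
    {"C_h5_object_exists",        (DL_FUNC) &C_h5_object_exists,        2},
    {"C_h5_obj_kind",             (DL_FUNC) &C_h5_obj_kind,             2},
    {"C_h5_ls",                   (DL_FUNC) &C_h5_ls,                   2},
    {"C_h5_link_kind",            (DL_FUNC) &C_h5_link_kind,            2},
    {"C_h5_external_link_target", (DL_FUNC) &C_h5_external_link_target, 2},
    {"C_h5_create_external_link", (DL_FUNC) &C_h5_create_external_link, 4},
    {"C_h5_delete_link",          (DL_FUNC) &C_h5_delete_link,          2},
    {"C_h5_make_dataset",         (DL_FUNC) &C_h5_make_dataset,         6},
    {"C_h5_dataset_dims",         (DL_FUNC) &C_h5_dataset_dims,         2},
    {"C_h5_read_dataset",         (DL_FUNC) &C_h5_read_dataset,         2},
    {"C_h5_set_extent",           (DL_FUNC) &C_h5_set_extent,           3},
    {"C_h5_write_hyperslab",      (DL_FUNC) &C_h5_write_hyperslab,      5},
    {"C_h5_write_attr",           (DL_FUNC) &C_h5_write_attr,           4},
    {"C_h5_read_attr",            (DL_FUNC) &C_h5_read_attr,            3},
    {"C_h5_attr_exists",          (DL_FUNC) &C_h5_attr_exists,          3},
    {"C_h5_attr_delete",          (DL_FUNC) &C_h5_attr_delete,          3},
    {"C_h5_ls_attrs",             (DL_FUNC) &C_h5_ls_attrs,             2},
    {"C_h5_ds_set_scale",         (DL_FUNC) &C_h5_ds_set_scale,         3},
    {"C_h5_ds_attach",            (DL_FUNC) &C_h5_ds_attach,            4},
    {"C_h5_ds_is_attached",       (DL_FUNC) &C_h5_ds_is_attached,       4},
    {NULL, NULL, 0}
};

void R_init_neurofmt(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
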