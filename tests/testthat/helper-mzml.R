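# Synthetic mzML fixture built in code (two MS1 spectra, uncompressed
# 64-bit float arrays): scan at 6 s with peaks (100.1, 5), (100.9, 7) and
# scan at 12 s with peak (102.2, 3).

writeMzmlFixture <- function(path) {
  b64 <- function(x)
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  spec <- function(i, rt, mz, inten) {
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>\n',
      '<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" ',
      'name="scan start time" value="%g" unitCvRef="UO" ',
      'unitAccession="UO:0000010" unitName="second"/></scan></scanList>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" ',
      'unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<binary>%s</binary></binaryDataArray>\n',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" ',
      'unitCvRef="MS" unitAccession="MS:1000131" ',
      'unitName="number of detector counts"/>',
      '<binary>%s</binary></binaryDataArray>\n',
      '</binaryDataArrayList></spectrum>'),
      i, i + 1, length(mz), rt, nchar(b64(mz)), b64(mz),
      nchar(b64(inten)), b64(inten))
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="x"/>',
    '<cv id="UO" fullName="UO" URI="y"/></cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>\n<run id="r1">\n',
    '<spectrumList count="2" defaultDataProcessingRef="dp">\n',
    spec(0, 6, c(100.1, 100.9), c(5, 7)), "\n",
    spec(1, 12, 102.2, 3),
    '\n</spectrumList></run></mzML>')
  writeLines(doc, path)
  invisible(path)
}
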