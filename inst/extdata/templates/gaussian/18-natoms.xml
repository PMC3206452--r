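<?xml version="1.0" encoding="UTF-8"?>
<template id="natoms" pattern="\s*NAtoms=.*" section="initialization">
  <record id="natoms">\s*NAtoms=\s*{1I, g:natoms}\s+NActive=\s*{1I, g:nactive}.*</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:natoms']" value="cc:natoms"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:nactive']" value="cc:nactiveatoms"/>
</template>
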