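<?xml version="1.0" encoding="UTF-8"?>
<!-- Thermochemistry summary: conditions, zero-point energy and corrections. -->
<template id="l716.thermo" pattern="\s*Temperature\s+[0-9.]+ Kelvin.*"
          section="finalization">
  <record id="tp">\s*Temperature\s+{1F, g:temp} Kelvin\.\s+Pressure\s+{1F, g:press} Atm\.\s*</record>
  <record id="zpe">\s*Zero-point vibrational energy\s+{1F, g:zpe} \(Joules/Mol\)\s*</record>
  <record id="zpecorr">\s*Zero-point correction=\s+{1F, g:zpecorr}.*</record>
  <record id="sumzpe">\s*Sum of electronic and zero-point Energies=\s+{1F, g:sumzpe}\s*</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:temp']" value="cc:temp"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:press']" value="cc:press"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:zpe']" value="cc:zpe"/>
  <transform process="addUnits" xpath=".//cml:scalar[@dictRef='cc:zpe']" value="u:jmol-1"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:zpecorr']" value="cc:zpe.correction"/>
  <transform process="addUnits" xpath=".//cml:scalar[@dictRef='cc:zpe.correction']" value="nonsi:hartree"/>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:sumzpe']" value="cc:zpe.sumelectzpe"/>
  <transform process="addUnits" xpath=".//cml:scalar[@dictRef='cc:zpe.sumelectzpe']" value="nonsi:hartree"/>
</template>
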